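#' Default run configuration
#'
#' Returns the fully resolved default configuration for [runPipeline()]:
#' a phantom input, truth-mask segmentation pathway, lateral projection at
#' isotropic spacing, and quantile thresholds 0.20 (sacrum outline) and
#' 0.90 (safe zone).
#'
#' @param outDir output directory.
#' @param seed integer seed recorded in the run and forwarded to the
#'   phantom generator.
#' @return a nested list understood by [runPipeline()].
#' @export
defaultRunConfig <- function(outDir = tempfile("sacrozone-run"), seed = 1L) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    input = list(volume = NULL, mask = NULL, traces = NULL),
    phantom = list(),                     # defaults of phantomSpec()
    segmentation = NULL,                  # NULL: use phantom truth / import
    projection = list(axis = "RL", isoMm = NULL, clampNegative = TRUE),
    safezone = list(outlineQuantile = 0.20, zoneQuantile = 0.90,
                    outlineThreshold = NULL, zoneThreshold = NULL,
                    select = "largest_area", seedMm = NULL)
  )
}

#' Read / write a run configuration as JSON
#'
#' `readRunConfig` validates that every referenced input path exists
#' before any computation starts.
#'
#' @param path JSON file.
#' @param config a configuration list.
#' @return the configuration list / the path, invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- defaultRunConfig()
  cfg <- utils::modifyList(base, cfg)
  validateRunConfig(cfg)
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

validateRunConfig <- function(config) {
  for (field in c("volume", "mask", "traces")) {
    p <- config$input[[field]]
    if (!is.null(p) && !file.exists(p))
      stop("config validation: input ", field, " path does not exist: ", p)
  }
  if (is.null(config$seed)) stop("config validation: seed is required")
  invisible(TRUE)
}

#' Run the full safe-zone pipeline
#'
#' Executes the end-to-end workflow: obtain a volume (load, or generate
#' the synthetic phantom), obtain a sacrum mask (import, rasterise
#' traces, threshold segmentation, or phantom ground truth), resample
#' volume and mask to isotropic spacing, compute masked and full lateral
#' projections, extract the sacrum outline contour, delineate the
#' high-density safe zone, render overlays, and write every artifact plus
#' a manifest with parameters and output hashes. All randomness flows
#' from the single config seed, so identical configurations reproduce
#' identical outputs hash-for-hash.
#'
#' Any stage error aborts with the stage name and cause; outputs written
#' up to that point are retained next to a `FAILED` marker naming the
#' stage.
#'
#' @param config nested list as from [defaultRunConfig()] /
#'   [readRunConfig()].
#' @return the manifest, invisibly (also written to
#'   `outDir/manifest.json`).
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  config <- utils::modifyList(defaultRunConfig(), config)
  validateRunConfig(config)
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  outputs <- character(0)
  stage <- "init"
  fail <- function(e) {
    writeLines(c(sprintf("stage: %s", stage), conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  emit <- function(path) outputs <<- c(outputs, path)

  manifest <- tryCatch({
    stage <- "input"
    phantom <- NULL
    if (!is.null(config$input$volume)) {
      vol <- loadVolume(config$input$volume)
    } else {
      pargs <- config$phantom
      pargs$seed <- config$seed
      spec <- do.call(phantomSpec, pargs)
      phantom <- generatePhantom(spec)
      vol <- phantom$volume
      writePhantomSpec(spec, file.path(outDir, "phantom_spec.json"))
      emit(file.path(outDir, "phantom_spec.json"))
      saveVolume(vol, file.path(outDir, "volume.nii"))
      emit(file.path(outDir, "volume.nii"))
      saveMask(phantom$truthMask, file.path(outDir, "truth_mask.nii"))
      emit(file.path(outDir, "truth_mask.nii"))
      saveMask(phantom$truthCore, file.path(outDir, "truth_core.nii"))
      emit(file.path(outDir, "truth_core.nii"))
    }

    stage <- "segmentation"
    if (!is.null(config$input$mask)) {
      mask <- loadMask(config$input$mask, vol)
      maskSource <- "imported"
    } else if (!is.null(config$input$traces)) {
      mask <- rasterizeTraces(readTraceCSV(config$input$traces), vol)
      maskSource <- "traces"
    } else if (!is.null(config$segmentation)) {
      sp <- config$segmentation
      params <- segmentationParams(
        huLow = sp$huLow,
        huHigh = if (is.null(sp$huHigh)) Inf else sp$huHigh,
        connectivity = if (is.null(sp$connectivity)) 26L else sp$connectivity,
        closingRadiusMm = if (is.null(sp$closingRadiusMm)) 2
                          else sp$closingRadiusMm)
      mask <- segmentSacrum(vol, params,
                            keepLargest = !isFALSE(sp$keepLargest))
      maskSource <- "threshold"
    } else if (!is.null(phantom)) {
      mask <- phantom$truthMask
      maskSource <- "phantom_truth"
    } else {
      stop("no mask pathway: provide input$mask, input$traces or ",
           "segmentation parameters")
    }
    if (sum(voxelData(mask)) == 0L)
      stop("segmentation produced an empty mask")
    saveMask(mask, file.path(outDir, "mask.nii"))
    emit(file.path(outDir, "mask.nii"))

    stage <- "resample"
    iso <- config$projection$isoMm
    volIso <- resampleIsotropic(vol, iso)
    maskIso <- resampleMaskIsotropic(mask, iso)

    stage <- "projection"
    axis <- config$projection$axis
    clamp <- !isFALSE(config$projection$clampNegative)
    pFull <- sumProjection(volIso, mask = NULL, axis = axis,
                           clampNegative = clamp)
    pMasked <- sumProjection(volIso, mask = maskIso, axis = axis,
                             clampNegative = clamp)
    for (nm in c("full", "masked")) {
      p <- if (nm == "full") pFull else pMasked
      writeProjection(p, file.path(outDir, paste0(nm, "_projection")))
      emit(file.path(outDir, paste0(nm, "_projection.tiff")))
      emit(file.path(outDir, paste0(nm, "_projection.png")))
      emit(file.path(outDir, paste0(nm, "_projection.json")))
    }

    stage <- "contours"
    szc <- config$safezone
    tOutline <- if (!is.null(szc$outlineThreshold)) szc$outlineThreshold
                else pickThreshold(pMasked, q = szc$outlineQuantile)
    contours <- extractContours(pMasked, tOutline)

    stage <- "safezone"
    tZone <- if (!is.null(szc$zoneThreshold)) szc$zoneThreshold
             else pickThreshold(pMasked, q = szc$zoneQuantile)
    zone <- delineateSafeZone(pMasked, tZone,
                              select = szc$select,
                              seedMm = unlist(szc$seedMm))
    writeZonePolygon(zone, csvPath = file.path(outDir, "zone.csv"),
                     geojsonPath = file.path(outDir, "zone.geojson"))
    emit(file.path(outDir, "zone.csv"))
    emit(file.path(outDir, "zone.geojson"))
    metrics <- zoneMetrics(zone)
    metrics$outlineThresholdHuMm <- tOutline
    metrics$zoneThresholdHuMm <- tZone
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(outDir, "metrics.json"))

    stage <- "overlay"
    overlay <- transferOutline(list(contours, zone), pFull)
    writeDisplayPNG(overlay, file.path(outDir, "overlay.png"))
    emit(file.path(outDir, "overlay.png"))

    stage <- "manifest"
    manifest <- list(
      package = "sacrozone",
      version = as.character(utils::packageVersion("sacrozone")),
      seed = config$seed,
      config = config,
      maskSource = maskSource,
      outputs = as.list(structure(
        as.character(tools::md5sum(outputs)),
        names = basename(outputs)))
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest
  }, error = fail)
  invisible(manifest)
}

## Projection artifact: normalised 32-bit float TIFF (with the intensity
## scale recorded in the JSON sidecar), an 8-bit windowed PNG, and the
## sidecar with pixel spacing, axis and provenance.
writeProjection <- function(projection, stem) {
  p <- projection@pixels
  scale <- max(max(p), 1e-12)
  tiff::writeTIFF(p / scale, paste0(stem, ".tiff"), bits.per.sample = 32L,
                  reduce = FALSE)
  writeDisplayPNG(windowDisplay(projection), paste0(stem, ".png"))
  jsonlite::write_json(
    list(pixel_spacing_mm = projection@pixelSpacing,
         summed_axis = projection@summedAxis,
         provenance = projection@provenance,
         source_id = projection@sourceId,
         intensity_scale_hu_mm = scale,
         units = "HU.mm (tiff pixel value x intensity_scale_hu_mm)"),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a projection written by the pipeline
#'
#' Reconstructs a [Projection2D-class] from the TIFF + JSON sidecar pair
#' produced by [runPipeline()] (float32 precision).
#'
#' @param stem path without extension, as written by the pipeline.
#' @return a [Projection2D-class].
#' @export
readProjection <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  p <- tiff::readTIFF(paste0(stem, ".tiff"))
  new("Projection2D", pixels = p * meta$intensity_scale_hu_mm,
      pixelSpacing = meta$pixel_spacing_mm,
      summedAxis = meta$summed_axis, provenance = meta$provenance,
      sourceId = meta$source_id)
}
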