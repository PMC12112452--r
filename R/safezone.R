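#' Pick a density threshold from a masked projection
#'
#' Nearest-rank quantile of the strictly positive pixel values (the
#' masked support). The source gives no numeric thresholds — the level is
#' "high enough to outline only the high density of S1" — so the package
#' parameterises the choice as a quantile of the observed density
#' distribution: `q = 0.20` for the sacrum outline contour and `q = 0.90`
#' for the safe zone by default. Absolute HU·mm values can be passed
#' straight to [extractContours()] / [delineateSafeZone()] instead.
#'
#' @param projection a [Projection2D-class] with at least one positive
#'   pixel.
#' @param method quantile is the only implemented rule.
#' @param q fraction in \[0, 1\]; nearest-rank: the `ceiling(q * n)`-th
#'   order statistic (the minimum at `q = 0`, the maximum at `q = 1`).
#' @return a single HU·mm value.
#' @export
pickThreshold <- function(projection, method = c("quantile"), q = 0.90) {
  method <- match.arg(method)
  stopifnot(is(projection, "Projection2D"))
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  v <- projection@pixels[projection@pixels > 0]
  if (length(v) == 0L)
    stop("pickThreshold: projection has no positive pixels")
  v <- sort(v)
  r <- max(1L, as.integer(ceiling(q * length(v))))
  v[r]
}

#' Delineate the high-density safe zone on a masked projection
#'
#' Binarises `P >= threshold`, labels 8-connected components, selects one
#' (largest area by default; an optional seed point in mm selects the
#' component containing it), and returns the region with its outer
#' boundary polygon, exact area and centroid. The method is defined on
#' the masked projection only: a full-field projection is rejected.
#'
#' Ties on component size are broken in favour of the component whose
#' minimal pixel (smallest row index, then smallest column index) comes
#' first — the superior/anterior-most region under the canonical axis
#' order.
#'
#' @param maskedProjection a masked [Projection2D-class].
#' @param threshold HU·mm binarisation level (e.g. from
#'   [pickThreshold()]).
#' @param select `"largest_area"` or `"seeded"`.
#' @param seedMm length-2 mm point required when `select = "seeded"`.
#' @return a [SafeZone-class].
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSd = 0))
#' iso <- resampleIsotropic(ph$volume)
#' msk <- resampleMaskIsotropic(ph$truthMask)
#' p <- sumProjection(iso, msk)
#' sz <- delineateSafeZone(p, pickThreshold(p, q = 0.90))
#' sz
delineateSafeZone <- function(maskedProjection, threshold,
                              select = c("largest_area", "seeded"),
                              seedMm = NULL) {
  select <- match.arg(select)
  stopifnot(is(maskedProjection, "Projection2D"))
  if (maskedProjection@provenance != "masked")
    stop("safe-zone delineation is defined on the masked projection; ",
         "got provenance '", maskedProjection@provenance, "'")
  if (!is.finite(threshold)) stop("threshold must be finite")
  P <- maskedProjection@pixels
  B <- P >= threshold
  if (!any(B))
    stop("NoRegion: no pixel at or above threshold ", threshold)
  lab <- labelComponents2D(B)
  du <- maskedProjection@pixelSpacing[1]
  dv <- maskedProjection@pixelSpacing[2]

  if (select == "largest_area") {
    sizes <- tabulate(lab[lab > 0L])
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      minKey <- function(label) {
        w <- which(lab == label, arr.ind = TRUE)
        w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
        w[1, ]
      }
      keys <- t(vapply(best, minKey, integer(2)))
      best <- best[order(keys[, 1], keys[, 2])[1]]
    }
    rule <- sprintf("largest_area (threshold %.6g)", threshold)
  } else {
    if (is.null(seedMm) || length(seedMm) != 2L)
      stop("select = 'seeded' requires seedMm = c(u, v)")
    i <- pmin(pmax(as.integer(ceiling(seedMm[1] / du)), 1L), nrow(P))
    j <- pmin(pmax(as.integer(ceiling(seedMm[2] / dv)), 1L), ncol(P))
    best <- lab[i, j]
    if (best == 0L)
      stop("NoRegion: seed point (", seedMm[1], ", ", seedMm[2],
           ") mm is not inside any super-threshold region")
    rule <- sprintf("seeded at (%.3f, %.3f) mm (threshold %.6g)",
                    seedMm[1], seedMm[2], threshold)
  }

  region <- matrix(as.integer(lab == best), nrow(P), ncol(P))
  w <- which(region == 1L, arr.ind = TRUE)
  centroid <- c(mean((w[, 1] - 0.5) * du), mean((w[, 2] - 0.5) * dv))
  ## outer boundary: 0.5-level contour of the binary region; the loop with
  ## the largest absolute enclosed area is the outer one.
  loops <- marchingSquares(region + 0, 0.5, du, dv)
  areas <- vapply(loops, function(p) abs(polygonArea(p)), numeric(1))
  poly <- loops[[which.max(areas)]]
  new("SafeZone", region = region, threshold = threshold, polygon = poly,
      areaMm2 = sum(region) * du * dv, centroidMm = centroid,
      pixelSpacing = c(du, dv), selectionRule = rule,
      sourceId = maskedProjection@sourceId)
}

#' Dice and Jaccard overlap coefficients
#'
#' @param a,b binary matrices/arrays of identical shape (nonzero =
#'   member).
#' @return `diceCoefficient`: `2|A∩B| / (|A|+|B|)`; `jaccardIndex`:
#'   `|A∩B| / |A∪B|`. Both are 1 when both regions are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' @rdname diceCoefficient
#' @export
jaccardIndex <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Metrics of a safe zone
#'
#' Area, centroid and bounding box of the zone; given a reference region
#' (e.g. a ground-truth footprint or a second observer's zone), also the
#' Dice and Jaccard overlap coefficients.
#'
#' @param zone a [SafeZone-class].
#' @param reference optional binary matrix with the zone's dimensions.
#' @return a list with `areaMm2`, `centroidMm`, `boundingBoxMm` (uMin,
#'   uMax, vMin, vMax over member pixel extents), `nPixels`, and, with a
#'   reference, `dice` and `jaccard`.
#' @export
zoneMetrics <- function(zone, reference = NULL) {
  stopifnot(is(zone, "SafeZone"))
  du <- zone@pixelSpacing[1]; dv <- zone@pixelSpacing[2]
  w <- which(zone@region == 1L, arr.ind = TRUE)
  out <- list(
    areaMm2 = zone@areaMm2,
    centroidMm = zone@centroidMm,
    boundingBoxMm = c(uMin = (min(w[, 1]) - 1) * du,
                      uMax = max(w[, 1]) * du,
                      vMin = (min(w[, 2]) - 1) * dv,
                      vMax = max(w[, 2]) * dv),
    nPixels = nrow(w)
  )
  if (!is.null(reference)) {
    out$dice <- diceCoefficient(zone@region, reference)
    out$jaccard <- jaccardIndex(zone@region, reference)
  }
  out
}

## Rasterise a polyline onto integer pixel indices by dense sampling of
## each segment (step << 1 px), for overlay drawing.
polylinePixels <- function(poly, du, dv, nr, nc) {
  out <- matrix(integer(0), 0, 2)
  for (e in seq_len(nrow(poly) - 1L)) {
    p <- poly[e, ]; q <- poly[e + 1L, ]
    L <- max(abs(q[1] - p[1]) / du, abs(q[2] - p[2]) / dv)
    n <- max(2L, ceiling(L * 3) + 1L)
    t <- seq(0, 1, length.out = n)
    i <- pmin(pmax(as.integer(ceiling((p[1] + t * (q[1] - p[1])) / du)), 1L), nr)
    j <- pmin(pmax(as.integer(ceiling((p[2] + t * (q[2] - p[2])) / dv)), 1L), nc)
    out <- rbind(out, cbind(i, j))
  }
  unique(out)
}

#' Transfer contour outlines onto the full projection
#'
#' Draws sacrum-outline contours and/or the safe-zone polygon onto the
#' windowed full-field projection. Masked and full projections of one
#' volume share the same pixel grid, so the transfer is
#' coordinate-identity; this is asserted (same `sourceId`, same grid),
#' not assumed. The outline is drawn in yellow and the safe zone in red
#' on the greyscale radiograph.
#'
#' @param outline a [ContourSet-class], a [SafeZone-class], or a list of
#'   such objects (empty contour sets are allowed and draw nothing).
#' @param fullProjection the full-field [Projection2D-class] from the
#'   same volume.
#' @param window,level display windowing passed to [windowDisplay()].
#' @return an RGB [DisplayImage-class].
#' @export
transferOutline <- function(outline, fullProjection, window = NULL,
                            level = NULL) {
  stopifnot(is(fullProjection, "Projection2D"))
  items <- if (is.list(outline)) outline else list(outline)
  base <- windowDisplay(fullProjection, window, level)
  g <- base@pixels / 255
  nr <- nrow(g); nc <- ncol(g)
  rgb <- array(rep(as.vector(g), 3), c(nr, nc, 3))
  du <- fullProjection@pixelSpacing[1]
  dv <- fullProjection@pixelSpacing[2]

  drawPolys <- function(polys, colour) {
    for (p in polys) {
      px <- polylinePixels(p, du, dv, nr, nc)
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[px] <- colour[ch]
        rgb[, , ch] <<- plane
      }
    }
  }

  for (it in items) {
    if (is(it, "ContourSet")) {
      if (!identical(it@sourceId, fullProjection@sourceId))
        stop("sourceId mismatch: outline from '", it@sourceId,
             "', projection from '", fullProjection@sourceId, "'")
      exU <- nr * du; exV <- nc * dv
      for (p in it@polylines)
        if (any(p[, 1] < -1e-9 | p[, 1] > exU + 1e-9 |
                p[, 2] < -1e-9 | p[, 2] > exV + 1e-9))
          stop("grid mismatch: contour vertices outside projection extent")
      drawPolys(it@polylines, c(1, 0.85, 0))       # yellow outline
    } else if (is(it, "SafeZone")) {
      if (!identical(it@sourceId, fullProjection@sourceId))
        stop("sourceId mismatch: safe zone from '", it@sourceId,
             "', projection from '", fullProjection@sourceId, "'")
      if (!isTRUE(all.equal(it@pixelSpacing, fullProjection@pixelSpacing)))
        stop("grid mismatch: safe zone pixel spacing differs from projection")
      drawPolys(list(it@polygon), c(1, 0.15, 0.15)) # red safe zone
    } else {
      stop("outline must be a ContourSet or SafeZone")
    }
  }
  new("DisplayImage", pixels = array(as.integer(round(rgb * 255)),
                                     c(nr, nc, 3)),
      pixelSpacing = fullProjection@pixelSpacing)
}

#' Write a display image as PNG
#'
#' @param image a [DisplayImage-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDisplayPNG <- function(image, path) {
  stopifnot(is(image, "DisplayImage"))
  png::writePNG(image@pixels / 255, path)
  invisible(path)
}

#' Write a safe-zone polygon as CSV and GeoJSON
#'
#' @param zone a [SafeZone-class].
#' @param csvPath,geojsonPath output paths (`NULL` to skip either).
#' @return invisibly, the written paths.
#' @export
writeZonePolygon <- function(zone, csvPath = NULL, geojsonPath = NULL) {
  stopifnot(is(zone, "SafeZone"))
  written <- character(0)
  if (!is.null(csvPath)) {
    utils::write.csv(data.frame(vertex_order = seq_len(nrow(zone@polygon)),
                                u_mm = zone@polygon[, 1],
                                v_mm = zone@polygon[, 2]),
                     csvPath, row.names = FALSE)
    written <- c(written, csvPath)
  }
  if (!is.null(geojsonPath)) {
    gj <- list(
      type = "Feature",
      properties = list(threshold_hu_mm = zone@threshold,
                        area_mm2 = zone@areaMm2,
                        centroid_mm = zone@centroidMm,
                        selection = zone@selectionRule),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(zone@polygon)),
                        function(i) zone@polygon[i, ])))
    )
    jsonlite::write_json(gj, geojsonPath, auto_unbox = TRUE, digits = NA)
    written <- c(written, geojsonPath)
  }
  invisible(written)
}
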