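#' Specify a synthetic pelvic CT phantom
#'
#' Builds a [PhantomSpec-class] describing an ellipsoidal sacral body with
#' a thin cortical shell, a denser S1 core, low-density foraminal
#' channels, surrounding soft tissue and seeded Gaussian noise. The
#' defaults emulate the osteopenic sacrum the method is aimed at: a
#' trabecular body at 150 HU sits well below the conventional +300 HU
#' cortical threshold, so naive HU thresholding visibly fails on the
#' phantom, while the 400 HU S1 core gives the masked lateral projection a
#' distinct high-density region with a known footprint.
#'
#' Default geometry (chosen once, on geometric grounds documented in the
#' methods vignette): 96 x 96 x 40 voxels at (0.672, 0.672, 2.976) mm;
#' body semi-axes (30, 25, 35) mm at the grid centre; 1.0 mm cortical
#' shell; core semi-axes (15, 9, 11) mm offset 15 mm superior; two
#' anteroposterior foraminal channels of radius 4 mm at +/-12 mm lateral
#' and 10 mm inferior of centre.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing numeric length-3 voxel pitch (mm).
#' @param bodyCenter,bodySemiaxes body ellipsoid (mm); `NULL` centres the
#'   body on the grid.
#' @param shellThickness cortical shell depth (mm).
#' @param coreCenter,coreSemiaxes S1 core ellipsoid (mm); `NULL` places
#'   the core 15 mm superior of the body centre.
#' @param foramina list of `list(center=, axis=, radius=)` cylinders;
#'   `NULL` gives the default pair.
#' @param huSoft,huTrabecular,huCortical,huCore,huForamen tissue HU
#'   levels.
#' @param noiseSd additive Gaussian noise standard deviation (HU).
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return a [PhantomSpec-class].
#' @export
#' @examples
#' spec <- phantomSpec(noiseSd = 0)
#' ph <- generatePhantom(spec)
#' ph$volume
phantomSpec <- function(shape = c(96L, 96L, 40L),
                        spacing = c(0.672, 0.672, 2.976),
                        bodyCenter = NULL,
                        bodySemiaxes = c(30, 25, 35),
                        shellThickness = 1.0,
                        coreCenter = NULL,
                        coreSemiaxes = c(15, 9, 11),
                        foramina = NULL,
                        huSoft = 40, huTrabecular = 150, huCortical = 700,
                        huCore = 400, huForamen = 20,
                        noiseSd = 20, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(bodyCenter)) bodyCenter <- shape * spacing / 2
  if (is.null(coreCenter)) coreCenter <- bodyCenter + c(0, 0, 15)
  if (is.null(foramina)) {
    foramina <- list(
      list(center = bodyCenter + c(-12, 0, -10), axis = 2L, radius = 4),
      list(center = bodyCenter + c(12, 0, -10), axis = 2L, radius = 4)
    )
  } else if (is.data.frame(foramina)) {
    ## tolerate the data.frame shape jsonlite produces for JSON configs
    foramina <- lapply(seq_len(nrow(foramina)), function(i)
      list(center = as.double(unlist(foramina$center[i])),
           axis = as.integer(foramina$axis[i]),
           radius = as.double(foramina$radius[i])))
  }
  new("PhantomSpec",
      shape = shape, spacing = as.double(spacing),
      bodyCenter = as.double(bodyCenter),
      bodySemiaxes = as.double(bodySemiaxes),
      shellThickness = as.double(shellThickness),
      coreCenter = as.double(coreCenter),
      coreSemiaxes = as.double(coreSemiaxes),
      foramina = foramina,
      huSoft = as.double(huSoft), huTrabecular = as.double(huTrabecular),
      huCortical = as.double(huCortical), huCore = as.double(huCore),
      huForamen = as.double(huForamen),
      noiseSd = as.double(noiseSd), seed = as.integer(seed))
}

## Quadratic form of an ellipsoid evaluated on coordinate vectors.
ellipsoidQ <- function(x, y, z, center, semi) {
  ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 +
    ((z - center[3]) / semi[3])^2
}

#' Generate a synthetic pelvic CT volume with ground truth
#'
#' Assigns HU by innermost-region-wins precedence (foramen over core over
#' cortical shell over trabecular body over soft tissue), adds seeded
#' Gaussian noise, and returns the volume together with the true sacrum
#' mask (body ellipsoid membership by voxel centre) and the true S1 core
#' mask. Generation is a pure function of the spec: identical specs give
#' bit-identical volumes.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with elements `volume` ([VoxelVolume-class]),
#'   `truthMask` and `truthCore` (both [BinaryMask-class]).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@shape
  sp <- spec@spacing
  cx <- axisCenters(d[1], sp[1])
  cy <- axisCenters(d[2], sp[2])
  cz <- axisCenters(d[3], sp[3])
  ## full coordinate grids (recycled column-major: x fastest)
  X <- array(rep(cx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)

  qBody <- ellipsoidQ(X, Y, Z, spec@bodyCenter, spec@bodySemiaxes)
  body <- qBody <= 1
  inner <- ellipsoidQ(X, Y, Z, spec@bodyCenter,
                      pmax(spec@bodySemiaxes - spec@shellThickness, 1e-6)) <= 1
  core <- ellipsoidQ(X, Y, Z, spec@coreCenter, spec@coreSemiaxes) <= 1

  hu <- array(spec@huSoft, d)
  hu[body] <- spec@huCortical            # shell by default inside body
  hu[body & inner] <- spec@huTrabecular  # interior overwrites shell
  hu[core] <- spec@huCore                # core wins over shell/trabecular
  for (f in spec@foramina) {
    ax <- as.integer(f$axis)
    inplane <- setdiff(1:3, ax)
    co <- list(X, Y, Z)
    r2 <- (co[[inplane[1]]] - f$center[inplane[1]])^2 +
          (co[[inplane[2]]] - f$center[inplane[2]])^2
    hu[body & (r2 <= f$radius^2)] <- spec@huForamen  # foramen wins over all
  }

  if (spec@noiseSd > 0) {
    rs <- .Random.seed.save()
    on.exit(.Random.seed.restore(rs), add = TRUE)
    set.seed(spec@seed)
    hu <- hu + array(stats::rnorm(prod(d), sd = spec@noiseSd), d)
  }

  vol <- VoxelVolume(hu, spacing = sp,
                     sourceId = sprintf("phantom-seed%d", spec@seed))
  list(volume = vol,
       truthMask = BinaryMask(body, spacing = sp),
       truthCore = BinaryMask(core, spacing = sp))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed.restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}

#' Ground-truth freehand traces of the phantom body
#'
#' Emits the analytic per-slice cross-section of the phantom's body
#' ellipsoid as closed polygons on transverse slices, emulating what an
#' operator tracing the sacrum boundary would produce. With the default
#' vertex count the inscribed polygon deviates from the true ellipse by
#' well under a hundredth of a millimetre, so rasterising these traces
#' recovers essentially the whole truth mask.
#'
#' @param spec a [PhantomSpec-class].
#' @param nVertices vertices per polygon (before closure).
#' @return a [PolygonTraceSet-class] on transverse slices (axis 3).
#' @export
phantomTraces <- function(spec, nVertices = 120L) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@shape
  sp <- spec@spacing
  cz <- axisCenters(d[3], sp[3])
  traces <- list()
  for (k in seq_len(d[3])) {
    w <- 1 - ((cz[k] - spec@bodyCenter[3]) / spec@bodySemiaxes[3])^2
    if (w <= 0) next
    a <- spec@bodySemiaxes[1] * sqrt(w)
    b <- spec@bodySemiaxes[2] * sqrt(w)
    th <- seq(0, 2 * pi, length.out = nVertices + 1L)
    v <- cbind(spec@bodyCenter[1] + a * cos(th),
               spec@bodyCenter[2] + b * sin(th))
    v[nVertices + 1L, ] <- v[1L, ]  # exact closure
    traces[[length(traces) + 1L]] <-
      list(slice = k - 1L, polygonId = 1L, vertices = v)
  }
  new("PolygonTraceSet", traces = traces, sliceAxis = 3L)
}

#' Analytic projection footprint of the phantom core
#'
#' The ground-truth footprint of the S1 core on a lateral (or other)
#' summation projection: a pixel is in the footprint iff the ray through
#' its centre along the summed axis intersects the core ellipsoid, which
#' for an axis-aligned ray reduces to an in-plane ellipse test.
#'
#' @param spec a [PhantomSpec-class].
#' @param projection a [Projection2D-class] defining the pixel grid.
#' @return integer matrix in \{0,1\} with the projection's dimensions.
#' @export
coreFootprint <- function(spec, projection) {
  stopifnot(is(spec, "PhantomSpec"), is(projection, "Projection2D"))
  ax <- resolveAxis(projection@summedAxis)
  inplane <- setdiff(1:3, ax)
  d <- dim(projection@pixels)
  cu <- axisCenters(d[1], projection@pixelSpacing[1])
  cv <- axisCenters(d[2], projection@pixelSpacing[2])
  U <- matrix(rep(cu, times = d[2]), d[1], d[2])
  V <- matrix(rep(cv, each = d[1]), d[1], d[2])
  q <- ((U - spec@coreCenter[inplane[1]]) / spec@coreSemiaxes[inplane[1]])^2 +
       ((V - spec@coreCenter[inplane[2]]) / spec@coreSemiaxes[inplane[2]])^2
  matrix(as.integer(q <= 1), d[1], d[2])
}

#' Serialize / restore a PhantomSpec as JSON
#'
#' @param spec a [PhantomSpec-class].
#' @param path JSON file path.
#' @return `writePhantomSpec` returns the path invisibly;
#'   `readPhantomSpec` returns a [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  obj <- list(
    shape = spec@shape, spacing = spec@spacing,
    bodyCenter = spec@bodyCenter, bodySemiaxes = spec@bodySemiaxes,
    shellThickness = spec@shellThickness,
    coreCenter = spec@coreCenter, coreSemiaxes = spec@coreSemiaxes,
    foramina = spec@foramina,
    huSoft = spec@huSoft, huTrabecular = spec@huTrabecular,
    huCortical = spec@huCortical, huCore = spec@huCore,
    huForamen = spec@huForamen, noiseSd = spec@noiseSd, seed = spec@seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  foramina <- o$foramina
  if (is.data.frame(foramina)) {
    foramina <- lapply(seq_len(nrow(foramina)), function(i)
      list(center = unlist(foramina$center[i]), axis = foramina$axis[i],
           radius = foramina$radius[i]))
  }
  phantomSpec(shape = o$shape, spacing = o$spacing,
              bodyCenter = o$bodyCenter, bodySemiaxes = o$bodySemiaxes,
              shellThickness = o$shellThickness, coreCenter = o$coreCenter,
              coreSemiaxes = o$coreSemiaxes, foramina = foramina,
              huSoft = o$huSoft, huTrabecular = o$huTrabecular,
              huCortical = o$huCortical, huCore = o$huCore,
              huForamen = o$huForamen, noiseSd = o$noiseSd, seed = o$seed)
}
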