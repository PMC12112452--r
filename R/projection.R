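#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto an isotropic grid covering the same
#' physical extent. The output axis lengths are `round(extent / target)`
#' (at least 1), so when the input is already isotropic at the target
#' spacing the output grid coincides with the input and values are copied
#' exactly. Sample positions within the half-voxel border band are
#' clamped to the nearest voxel centre (nearest-edge extension).
#'
#' CT acquisitions are strongly anisotropic (the target geometry here is
#' 0.672 mm in-plane against 2.976 mm between slices); projecting without
#' resampling would give rectangular pixels, so the pipeline resamples
#' first and projects second.
#'
#' @param volume a [VoxelVolume-class].
#' @param targetMm isotropic spacing in mm; default = smallest source
#'   spacing component.
#' @return a [VoxelVolume-class] with spacing `c(t, t, t)`.
#' @export
resampleIsotropic <- function(volume, targetMm = NULL) {
  stopifnot(is(volume, "VoxelVolume"))
  if (is.null(targetMm)) targetMm <- min(volume@spacing)
  if (targetMm <= 0) stop("targetMm must be positive")
  d <- dim(volume@data)
  extent <- d * volume@spacing
  if (targetMm > max(extent))
    stop("targetMm (", targetMm, " mm) exceeds every physical extent (max ",
         sprintf("%.3f", max(extent)), " mm)")
  nOut <- pmax(1L, as.integer(round(extent / targetMm)))
  dat <- trilinearResample(volume@data, volume@spacing, nOut,
                           rep(targetMm, 3))
  VoxelVolume(dat, spacing = rep(targetMm, 3), origin = volume@origin,
              sourceId = volume@sourceId)
}

## Vectorised trilinear interpolation of `arr` (spacing spIn) at the centre
## grid of an nOut-shaped grid with spacing spOut over the same extent.
trilinearResample <- function(arr, spIn, nOut, spOut) {
  d <- dim(arr)
  ## fractional 0-based input indices of output voxel centres
  fr <- lapply(1:3, function(a) {
    u <- (seq_len(nOut[a]) - 0.5) * spOut[a]   # physical position
    f <- u / spIn[a] - 0.5
    pmin(pmax(f, 0), d[a] - 1)                 # clamp to centre range
  })
  i0 <- lapply(1:3, function(a) pmin(floor(fr[[a]]), d[[a]] - 1))
  w  <- lapply(1:3, function(a) fr[[a]] - i0[[a]])
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1, d[[a]] - 1))

  ## expand per-axis vectors to the full output grid (column-major)
  ex <- function(v, axis) {
    if (axis == 1) array(rep(v, times = nOut[2] * nOut[3]), nOut)
    else if (axis == 2) array(rep(rep(v, each = nOut[1]), times = nOut[3]), nOut)
    else array(rep(v, each = nOut[1] * nOut[2]), nOut)
  }
  I0 <- lapply(1:3, function(a) ex(i0[[a]], a))
  I1 <- lapply(1:3, function(a) ex(i1[[a]], a))
  W  <- lapply(1:3, function(a) ex(w[[a]], a))

  gather <- function(ix, iy, iz) {
    lin <- 1 + ix + d[1] * (iy + d[2] * iz)
    array(arr[lin], nOut)
  }
  c000 <- gather(I0[[1]], I0[[2]], I0[[3]])
  c100 <- gather(I1[[1]], I0[[2]], I0[[3]])
  c010 <- gather(I0[[1]], I1[[2]], I0[[3]])
  c110 <- gather(I1[[1]], I1[[2]], I0[[3]])
  c001 <- gather(I0[[1]], I0[[2]], I1[[3]])
  c101 <- gather(I1[[1]], I0[[2]], I1[[3]])
  c011 <- gather(I0[[1]], I1[[2]], I1[[3]])
  c111 <- gather(I1[[1]], I1[[2]], I1[[3]])
  wx <- W[[1]]; wy <- W[[2]]; wz <- W[[3]]
  (1 - wz) * ((1 - wy) * ((1 - wx) * c000 + wx * c100) +
              wy * ((1 - wx) * c010 + wx * c110)) +
    wz * ((1 - wy) * ((1 - wx) * c001 + wx * c101) +
          wy * ((1 - wx) * c011 + wx * c111))
}

#' Resample a binary mask to isotropic spacing
#'
#' Trilinear interpolation of the 0/1 field followed by a 0.5 cut, which
#' keeps the mask congruent with the matching [resampleIsotropic()]
#' output.
#'
#' @param mask a [BinaryMask-class].
#' @param targetMm isotropic spacing in mm; default = smallest source
#'   spacing component.
#' @return a [BinaryMask-class].
#' @export
resampleMaskIsotropic <- function(mask, targetMm = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  if (is.null(targetMm)) targetMm <- min(mask@spacing)
  d <- dim(mask@data)
  extent <- d * mask@spacing
  if (targetMm > max(extent)) stop("targetMm exceeds every physical extent")
  nOut <- pmax(1L, as.integer(round(extent / targetMm)))
  dat <- trilinearResample(mask@data + 0, mask@spacing, nOut,
                           rep(targetMm, 3))
  BinaryMask(dat >= 0.5, spacing = rep(targetMm, 3), origin = mask@origin)
}

#' Density-summation projection (virtual radiograph)
#'
#' Computes `P(i, j) = sum_k w(v) * ds` along the chosen canonical axis,
#' where `ds` is the voxel pitch along that axis and `w` clamps negative
#' HU to zero when `clampNegative` is on, so pixel values are line
#' integrals in HU·mm. With a mask, voxels outside it contribute nothing
#' ("eclipsing everything outside the mask") and the projection's
#' provenance is `"masked"`; safe-zone delineation requires a masked
#' projection.
#'
#' Negative-HU clamping defaults on: air at -1000 HU would otherwise
#' dominate the full-field sums the method reads as bone density. The
#' masked projection is insensitive to the flag because the mask excludes
#' air.
#'
#' Slices are accumulated in ascending index order, each pre-multiplied
#' by `ds`, so the per-pixel floating-point summation order equals that
#' of a plain ascending triple loop.
#'
#' @param volume a [VoxelVolume-class].
#' @param mask optional [BinaryMask-class], grid-congruent with `volume`
#'   and non-empty.
#' @param axis `"RL"` (lateral, default), `"AP"`, `"IS"`, a clinical
#'   synonym (`"lateral"`, `"ap"`, `"axial"`), or an axis index.
#' @param clampNegative clamp negative HU to 0 before summing.
#' @return a [Projection2D-class].
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSd = 0))
#' p <- sumProjection(ph$volume, ph$truthMask, axis = "lateral")
#' p
sumProjection <- function(volume, mask = NULL, axis = "RL",
                          clampNegative = TRUE) {
  stopifnot(is(volume, "VoxelVolume"))
  a <- resolveAxis(axis)
  d <- dim(volume@data)
  if (!is.null(mask)) {
    stopifnot(is(mask, "BinaryMask"))
    checkCongruent(mask, volume)
    if (sum(mask@data) == 0L)
      stop("sumProjection: mask is empty")
  }
  ds <- volume@spacing[a]
  inplane <- setdiff(1:3, a)
  acc <- matrix(0, d[inplane[1]], d[inplane[2]])
  slice3 <- function(arr, k) {
    if (a == 1L) arr[k, , ]
    else if (a == 2L) arr[, k, ]
    else arr[, , k]
  }
  for (k in seq_len(d[a])) {
    s <- slice3(volume@data, k)
    if (clampNegative) s <- pmax(s, 0)
    if (!is.null(mask)) s <- s * slice3(mask@data, k)
    acc <- acc + s * ds
  }
  new("Projection2D",
      pixels = acc,
      pixelSpacing = volume@spacing[inplane],
      summedAxis = canonicalAxisLabel(a),
      provenance = if (is.null(mask)) "full" else "masked",
      sourceId = volume@sourceId)
}

#' Window a projection into an 8-bit display image
#'
#' Linear map of `[level - window/2, level + window/2]` onto 0..255 with
#' clipping, the usual radiological window/level display transform.
#'
#' @param projection a [Projection2D-class].
#' @param window window width (HU·mm), `> 0`. Default: the full positive
#'   intensity range.
#' @param level window centre (HU·mm). Default: midpoint of the range.
#' @return a greyscale [DisplayImage-class].
#' @export
windowDisplay <- function(projection, window = NULL, level = NULL) {
  stopifnot(is(projection, "Projection2D"))
  p <- projection@pixels
  if (is.null(window)) window <- max(max(p) - min(p), 1e-12)
  if (is.null(level)) level <- (max(p) + min(p)) / 2
  if (window <= 0) stop("window width must be positive")
  lo <- level - window / 2
  v <- round(pmin(pmax((p - lo) / window, 0), 1) * 255)
  new("DisplayImage", pixels = array(as.integer(v), dim(p)),
      pixelSpacing = projection@pixelSpacing)
}
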