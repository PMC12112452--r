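#' Segmentation parameters
#'
#' @param huLow lower HU threshold (inclusive).
#' @param huHigh upper HU threshold (inclusive), default `Inf`.
#' @param connectivity voxel connectivity for component analysis, 6 or 26.
#'   Default 26: the large longitudinal spacing (2.976 mm) would otherwise
#'   disconnect thin oblique structures.
#' @param closingRadiusMm morphological closing radius in mm (default 2).
#' @return a plain list of validated parameters.
#' @export
segmentationParams <- function(huLow, huHigh = Inf, connectivity = 26L,
                               closingRadiusMm = 2) {
  if (!(huLow < huHigh)) stop("huLow must be below huHigh")
  if (!(connectivity %in% c(6L, 26L))) stop("connectivity must be 6 or 26")
  if (closingRadiusMm < 0) stop("closingRadiusMm must be >= 0")
  list(huLow = huLow, huHigh = huHigh,
       connectivity = as.integer(connectivity),
       closingRadiusMm = closingRadiusMm)
}

#' Threshold a volume into a binary mask
#'
#' A voxel becomes a member iff `huLow <= value <= huHigh`. An empty
#' result is the documented failure mode of plain HU thresholding on
#' low-density bone: it raises a warning, not an error, and returns the
#' empty mask so callers can observe the failure.
#'
#' @param volume a [VoxelVolume-class].
#' @param params list from [segmentationParams()], or a single `huLow`
#'   number.
#' @return a [BinaryMask-class] (possibly empty).
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSd = 0))
#' m <- thresholdMask(ph$volume, segmentationParams(huLow = 300))
#' sum(voxelData(m)) / sum(voxelData(ph$truthMask))  # fragmented shell only
thresholdMask <- function(volume, params) {
  stopifnot(is(volume, "VoxelVolume"))
  if (is.numeric(params)) params <- segmentationParams(huLow = params)
  m <- volume@data >= params$huLow & volume@data <= params$huHigh
  if (!any(m))
    warning("thresholding produced an empty mask (huLow = ", params$huLow,
            ", huHigh = ", params$huHigh, ")", call. = FALSE)
  BinaryMask(m, spacing = volume@spacing, origin = volume@origin)
}

#' Keep only the largest connected component of a mask
#'
#' Components are found under the stated voxel connectivity; ties on size
#' are broken deterministically in favour of the component containing the
#' lexicographically smallest (i, j, k) voxel index.
#'
#' @param mask a non-empty [BinaryMask-class].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return a [BinaryMask-class] containing one component.
#' @export
largestComponent <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"))
  if (!(connectivity %in% c(6L, 26L))) stop("connectivity must be 6 or 26")
  if (sum(mask@data) == 0L) stop("largestComponent: mask is empty")
  lab <- label_components_cpp(mask@data != 0L, dim(mask@data),
                              as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ## lexicographic (i, j, k) tie-break
    minKey <- function(label) {
      w <- which(lab == label, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
      w[1, ]
    }
    keys <- t(vapply(best, minKey, integer(3)))
    best <- best[order(keys[, 1], keys[, 2], keys[, 3])[1]]
  }
  BinaryMask(lab == best, spacing = mask@spacing, origin = mask@origin)
}

#' Morphological closing with an ellipsoidal structuring element
#'
#' Dilation followed by erosion with an element whose mm radius converts
#' per-axis through the voxel spacing, so the element is isotropic in
#' physical space even on anisotropic grids. The grid is padded by the
#' element radius before dilation so closing is extensive (never removes
#' input voxels) regardless of border contact. Radius 0 is the identity.
#'
#' @param mask a [BinaryMask-class].
#' @param radiusMm closing radius in mm, `>= 0`.
#' @return a [BinaryMask-class].
#' @export
closeMask <- function(mask, radiusMm) {
  stopifnot(is(mask, "BinaryMask"))
  if (radiusMm < 0) stop("radiusMm must be >= 0")
  offs <- ellipsoidOffsets(radiusMm, mask@spacing)
  if (nrow(offs) <= 1L) return(mask)
  pad <- apply(abs(offs), 2, max)
  d <- dim(mask@data)
  dp <- d + 2L * pad
  padded <- array(FALSE, dp)
  padded[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
         pad[3] + seq_len(d[3])] <- mask@data != 0L
  dil <- binary_dilate_cpp(padded, dp, offs)
  ero <- binary_erode_cpp(dil, dp, offs)
  ero <- array(ero, dp)
  out <- ero[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
             pad[3] + seq_len(d[3])]
  BinaryMask(out, spacing = mask@spacing, origin = mask@origin)
}

#' Threshold-and-clean sacrum segmentation
#'
#' Convenience composition of the thresholding pathway:
#' [thresholdMask()], optionally [largestComponent()], then
#' [closeMask()]. On low-density bone this pathway is expected to fail to
#' produce a solid sacrum (the shell and core fragment apart); the
#' freehand pathway ([rasterizeTraces()] or [loadMask()]) is the
#' fallback, mirroring clinical practice.
#'
#' @param volume a [VoxelVolume-class].
#' @param params from [segmentationParams()].
#' @param keepLargest retain only the largest component before closing.
#' @return a [BinaryMask-class].
#' @export
segmentSacrum <- function(volume, params, keepLargest = TRUE) {
  m <- thresholdMask(volume, params)
  if (keepLargest && sum(m@data) > 0L)
    m <- largestComponent(m, params$connectivity)
  if (params$closingRadiusMm > 0 && sum(m@data) > 0L)
    m <- closeMask(m, params$closingRadiusMm)
  m
}
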