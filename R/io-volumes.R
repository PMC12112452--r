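#' Construct a VoxelVolume
#'
#' @param data numeric 3D array of HU values in canonical RL-AP-IS order.
#' @param spacing numeric length-3 voxel pitch in mm.
#' @param origin numeric length-3 mm origin (voxel centre = origin +
#'   (index0 + 0.5) * spacing).
#' @param sourceId character identifier for provenance tracking.
#' @return a [VoxelVolume-class].
#' @export
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 2)), spacing = c(0.672, 0.672, 2.976))
#' spacing(v)
VoxelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        sourceId = "volume") {
  new("VoxelVolume", data = array(as.double(data), dim(data)),
      spacing = as.double(spacing), origin = as.double(origin),
      orientation = "RL-AP-IS", sourceId = as.character(sourceId))
}

#' Construct a BinaryMask
#'
#' @param data array coercible to 0/1; any nonzero value counts as
#'   membership.
#' @param spacing,origin grid geometry, normally inherited from the parent
#'   volume.
#' @return a [BinaryMask-class].
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- array(as.integer(data != 0), dim(data))
  new("BinaryMask", data = d, spacing = as.double(spacing),
      origin = as.double(origin))
}

## LPS-coded qform for a canonical volume (axis 1 to patient left is -x in
## NIfTI's RAS world, axis 2 to posterior is -y, axis 3 to superior is +z).
canonicalQform <- function(spacing, origin = c(0, 0, 0)) {
  x <- diag(4)
  diag(x)[1:3] <- c(-1, -1, 1) * spacing
  x[1:3, 4] <- c(-1, -1, 1) * (origin + 0.5 * spacing)
  structure(x, code = 1L)
}

#' Load a CT volume from NIfTI or a DICOM series directory
#'
#' Reads a scalar CT volume and returns it in the canonical RL-AP-IS axis
#' order. For NIfTI, images carrying a qform/sform are reoriented to LPS
#' axis codes (a pure permutation/flip, so the multiset of voxel values is
#' preserved); images without any transform are assumed already canonical.
#' For DICOM, the rescale slope and intercept are applied so values are
#' Hounsfield units, slices are sorted by their patient-space z position,
#' and non-uniform slice gaps beyond 1\% of the nominal gap are a hard
#' error.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of DICOM slices.
#' @param format `"nifti"`, `"dicom_dir"`, or `"auto"` (directory implies
#'   DICOM).
#' @return a [VoxelVolume-class].
#' @seealso [saveVolume()], [loadMask()]
#' @export
loadVolume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "dicom_dir") return(loadDicomSeries(path))

  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
    RNifti::orientation(img) <- "LPS"
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or contradictory spacing metadata in ", path)
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
    dat <- array(dat, dim(dat)[1:3])
  if (length(dim(dat)) != 3L)
    stop("expected a 3D volume, got ", length(dim(dat)), " dimensions")
  VoxelVolume(dat, spacing = sp, sourceId = basename(path))
}

#' Save a CT volume as NIfTI
#'
#' Writes the canonical volume as uncompressed NIfTI with float64 data so
#' that [loadVolume()] recovers it bit-identically, with an LPS-coded
#' qform carrying the spacing.
#'
#' @param volume a [VoxelVolume-class].
#' @param path output `.nii` path.
#' @return invisibly, the path.
#' @export
saveVolume <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::qform(img) <- canonicalQform(volume@spacing, volume@origin)
  RNifti::pixdim(img) <- volume@spacing
  out <- try(RNifti::writeNifti(img, path, datatype = "double"),
             silent = TRUE)
  if (inherits(out, "try-error") || !file.exists(path))
    stop("could not write volume to ", path)
  invisible(path)
}

#' Load a binary mask congruent with a parent volume
#'
#' Any nonzero stored value counts as membership; values are coerced to
#' \{0, 1\}. Shape must match the parent exactly and spacing to within
#' 1e-3 mm, otherwise a grid-mismatch error is raised.
#'
#' @param path a NIfTI mask file.
#' @param parent the parent [VoxelVolume-class].
#' @return a [BinaryMask-class].
#' @export
loadMask <- function(path, parent) {
  stopifnot(is(parent, "VoxelVolume"))
  if (!file.exists(path)) stop("path does not exist: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
    RNifti::orientation(img) <- "LPS"
  sp <- RNifti::pixdim(img)[1:3]
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
    dat <- array(dat, dim(dat)[1:3])
  m <- BinaryMask(dat, spacing = sp, origin = parent@origin)
  checkCongruent(m, parent)
  m
}

#' Save a binary mask as unsigned 8-bit NIfTI
#'
#' @param mask a [BinaryMask-class].
#' @param path output `.nii` path.
#' @return invisibly, the path.
#' @export
saveMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  img <- RNifti::asNifti(mask@data)
  RNifti::pixdim(img) <- mask@spacing
  RNifti::qform(img) <- canonicalQform(mask@spacing, mask@origin)
  RNifti::pixdim(img) <- mask@spacing
  out <- try(RNifti::writeNifti(img, path, datatype = "uint8"),
             silent = TRUE)
  if (inherits(out, "try-error") || !file.exists(path))
    stop("could not write mask to ", path)
  invisible(path)
}

#' Read freehand tracings from CSV
#'
#' The CSV stands in for slicewise freehand segmentation: columns
#' `slice_index` (0-based), `polygon_id`, `vertex_order`, `x_mm`, `y_mm`,
#' one row per vertex. Each polygon is normalised to explicit closure
#' (first vertex appended if absent).
#'
#' @param path CSV file.
#' @param sliceAxis canonical axis the tracing planes are orthogonal to
#'   (default 3, transverse slices).
#' @return a [PolygonTraceSet-class].
#' @export
readTraceCSV <- function(path, sliceAxis = 3L) {
  df <- utils::read.csv(path)
  need <- c("slice_index", "polygon_id", "vertex_order", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  keys <- unique(df[, c("slice_index", "polygon_id")])
  traces <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- df[df$slice_index == keys$slice_index[r] &
              df$polygon_id == keys$polygon_id[r], ]
    sub <- sub[order(sub$vertex_order), ]
    v <- cbind(sub$x_mm, sub$y_mm)
    if (nrow(v) < 3L) stop("polygon with < 3 vertices in ", path)
    if (any(v[1, ] != v[nrow(v), ])) v <- rbind(v, v[1, ])
    list(slice = keys$slice_index[r], polygonId = keys$polygon_id[r],
         vertices = v)
  })
  new("PolygonTraceSet", traces = traces, sliceAxis = as.integer(sliceAxis))
}

#' Write a PolygonTraceSet to CSV
#'
#' @param traces a [PolygonTraceSet-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeTraceCSV <- function(traces, path) {
  stopifnot(is(traces, "PolygonTraceSet"))
  rows <- do.call(rbind, lapply(traces@traces, function(tr) {
    data.frame(slice_index = tr$slice, polygon_id = tr$polygonId,
               vertex_order = seq_len(nrow(tr$vertices)),
               x_mm = tr$vertices[, 1], y_mm = tr$vertices[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Rasterize freehand polygon tracings into a binary mask
#'
#' A voxel becomes a member iff its physical centre lies inside the traced
#' polygon(s) of its slice under the even-odd rule; boundary-touching
#' centres count as inside. Multiple polygons on one slice combine by
#' joint even-odd parity, so a polygon inside another cuts a hole.
#' Slices with no trace are empty; a polygon lying entirely outside the
#' grid yields an empty slice with a warning.
#'
#' @param traces a [PolygonTraceSet-class].
#' @param parent the parent [VoxelVolume-class] defining the grid.
#' @param rule fill rule; only `"even_odd"` is defined.
#' @return a [BinaryMask-class] congruent with `parent`.
#' @export
rasterizeTraces <- function(traces, parent, rule = c("even_odd")) {
  rule <- match.arg(rule)
  stopifnot(is(traces, "PolygonTraceSet"), is(parent, "VoxelVolume"))
  dims <- dim(parent@data)
  ax <- traces@sliceAxis
  inplane <- setdiff(1:3, ax)
  nU <- dims[inplane[1]]; nV <- dims[inplane[2]]
  cu <- axisCenters(nU, parent@spacing[inplane[1]], parent@origin[inplane[1]])
  cv <- axisCenters(nV, parent@spacing[inplane[2]], parent@origin[inplane[2]])
  grid <- expand.grid(u = cu, v = cv)

  out <- array(0L, dims)
  slices <- vapply(traces@traces, function(tr) as.integer(tr$slice),
                   integer(1))
  if (length(slices) && (min(slices) < 0L || max(slices) >= dims[ax]))
    stop("trace slice index out of volume bounds")
  for (s in unique(slices)) {
    polys <- lapply(traces@traces[slices == s], `[[`, "vertices")
    for (p in polys) if (nrow(p) < 4L) stop("polygon with < 3 vertices")
    member <- pointsInPolygonsEO(grid$u, grid$v, polys)
    if (!any(member)) {
      warning("trace on slice ", s, " covers no voxel centre", call. = FALSE)
      next
    }
    plane <- matrix(as.integer(member), nU, nV)
    if (ax == 3L) out[, , s + 1L] <- plane
    else if (ax == 2L) out[, s + 1L, ] <- plane
    else out[s + 1L, , ] <- plane
  }
  BinaryMask(out, spacing = parent@spacing, origin = parent@origin)
}
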