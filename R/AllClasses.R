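#' @useDynLib sacrozone, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## Canonical axis order used throughout: axis 1 runs right -> left,
## axis 2 anterior -> posterior, axis 3 inferior -> superior ("LPS" codes).
## A voxel's physical centre is origin + (index0 + 0.5) * spacing, with
## 0-based indices, so geometry (rasterisation, areas) is exact and testable.

CANONICAL_AXES <- c("RL", "AP", "IS")

#' VoxelVolume: a 3D CT grid in Hounsfield units
#'
#' Container for a scalar CT volume with per-axis spacing in mm, an origin,
#' and a fixed canonical orientation (axis 1 right to left, axis 2 anterior
#' to posterior, axis 3 inferior to superior). Values are Hounsfield units
#' (HU); values outside the plausible CT range \[-1100, 4000\] HU raise a
#' warning at validation, not an error, since headers and metal artefacts
#' occasionally exceed it.
#'
#' @slot data numeric 3D array of HU values.
#' @slot spacing numeric length-3, voxel pitch in mm per canonical axis.
#' @slot origin numeric length-3, mm position such that voxel centre
#'   = origin + (index0 + 0.5) * spacing.
#' @slot orientation character scalar, fixed to "RL-AP-IS".
#' @slot sourceId character scalar identifying the originating dataset.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(
    data        = "array",
    spacing     = "numeric",
    origin      = "numeric",
    orientation = "character",
    sourceId    = "character"
  ),
  prototype(
    spacing = c(1, 1, 1), origin = c(0, 0, 0),
    orientation = "RL-AP-IS", sourceId = "volume"
  )
)

setValidity("VoxelVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (any(dim(d) < 1L)) return("each axis must have length >= 1")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three strictly positive finite values (mm)")
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be three finite values (mm)")
  if (!all(is.finite(d))) return("all voxel values must be finite")
  if (!identical(object@orientation, "RL-AP-IS"))
    return("orientation must be the canonical 'RL-AP-IS'")
  rng <- range(d)
  if (rng[1] < -1100 || rng[2] > 4000)
    warning("voxel values outside [-1100, 4000] HU: range ",
            sprintf("[%.1f, %.1f]", rng[1], rng[2]), call. = FALSE)
  TRUE
})

#' BinaryMask: voxelwise membership grid congruent with a parent volume
#'
#' A 0/1 grid marking segmented voxels (here, the sacrum). Grid shape and
#' spacing must match the parent [VoxelVolume-class] exactly; emptiness is
#' permitted at construction (thresholding is allowed to fail and callers
#' must be able to observe that) but operations that consume a mask require
#' at least one member voxel.
#'
#' @slot data integer 3D array with values in \{0, 1\}.
#' @slot spacing numeric length-3 mm, inherited from the parent volume.
#' @slot origin numeric length-3 mm.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("BinaryMask", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (!all(d %in% c(0L, 1L))) return("mask values must be 0 or 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three strictly positive finite values (mm)")
  TRUE
})

#' PolygonTraceSet: slicewise freehand tracings as closed polygons
#'
#' Stand-in for manual freehand segmentation: each trace is a closed
#' polygon in in-plane mm coordinates attached to one slice of the parent
#' volume. Polygons are normalised so the first vertex equals the last.
#'
#' @slot traces list; each element a list with `slice` (0-based slice
#'   index), `polygonId` (integer) and `vertices` (n x 2 matrix, mm,
#'   closed).
#' @slot sliceAxis integer in 1..3: the canonical axis the tracing planes
#'   are orthogonal to (3 = transverse slices, the usual case).
#' @exportClass PolygonTraceSet
setClass("PolygonTraceSet",
  representation(traces = "list", sliceAxis = "integer"),
  prototype(sliceAxis = 3L)
)

setValidity("PolygonTraceSet", function(object) {
  if (!(object@sliceAxis %in% 1:3)) return("sliceAxis must be 1, 2 or 3")
  for (tr in object@traces) {
    v <- tr$vertices
    if (!is.matrix(v) || ncol(v) != 2L)
      return("each trace needs an n x 2 vertex matrix")
    if (nrow(v) < 4L)
      return("each polygon needs >= 3 distinct vertices (closed: first = last)")
    if (!isTRUE(all.equal(v[1, ], v[nrow(v), ], tolerance = 1e-9,
                          check.attributes = FALSE)))
      return("polygons must be closed (first vertex = last vertex)")
    if (!is.numeric(tr$slice) || tr$slice < 0)
      return("slice indices must be non-negative")
  }
  TRUE
})

#' Projection2D: a density-summation image in HU·mm
#'
#' The virtual radiograph obtained by summing HU values along one canonical
#' axis, weighted by the voxel pitch along that axis, so pixel values are
#' line integrals in HU·mm. `provenance` records whether everything outside
#' a sacrum mask was eclipsed ("masked") or the whole field contributed
#' ("full"); the safe-zone delineation is only defined on masked
#' projections.
#'
#' @slot pixels numeric matrix, HU·mm; rows follow the first retained
#'   canonical axis, columns the second.
#' @slot pixelSpacing numeric length-2 mm for the retained axes.
#' @slot summedAxis character, one of "RL", "AP", "IS".
#' @slot provenance character, "full" or "masked".
#' @slot sourceId character tying the projection to its source volume.
#' @exportClass Projection2D
setClass("Projection2D",
  representation(
    pixels = "matrix", pixelSpacing = "numeric", summedAxis = "character",
    provenance = "character", sourceId = "character"
  ),
  prototype(provenance = "full", sourceId = "volume")
)

setValidity("Projection2D", function(object) {
  if (!all(is.finite(object@pixels))) return("pixel values must be finite")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values (mm)")
  if (!(object@summedAxis %in% CANONICAL_AXES))
    return("summedAxis must be one of 'RL', 'AP', 'IS'")
  if (!(object@provenance %in% c("full", "masked")))
    return("provenance must be 'full' or 'masked'")
  TRUE
})

#' ContourSet: closed iso-density polylines on a projection
#'
#' Closed sub-pixel iso-lines of the super-level set \{P >= threshold\} of a
#' projection, extracted by marching squares with linear interpolation.
#' Vertices are in projection mm coordinates (u along rows, v along
#' columns).
#'
#' @slot polylines list of closed k x 2 matrices (first row = last row).
#' @slot threshold numeric, the HU·mm level that generated the contours.
#' @slot sourceId character, the originating projection's source.
#' @exportClass ContourSet
setClass("ContourSet",
  representation(polylines = "list", threshold = "numeric",
                 sourceId = "character"),
  prototype(sourceId = "volume")
)

setValidity("ContourSet", function(object) {
  for (p in object@polylines) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 4L)
      return("each polyline must be a closed k x 2 matrix with >= 4 rows")
    if (!isTRUE(all.equal(p[1, ], p[nrow(p), ], tolerance = 1e-9,
                          check.attributes = FALSE)))
      return("each polyline must be closed (first vertex = last)")
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    return("threshold must be a single finite value")
  TRUE
})

#' SafeZone: the high-density screw-target region on the masked projection
#'
#' A single 8-connected pixel region of the masked projection above a high
#' density threshold, with its outer boundary polygon, exact pixel area and
#' centroid. This region marks where summed bone density is highest, i.e.
#' where a sacroiliac screw is most likely to remain intraosseous.
#'
#' @slot region integer matrix in \{0,1\}, the selected component.
#' @slot threshold numeric HU·mm used for binarisation.
#' @slot polygon closed n x 2 matrix (mm), outer boundary.
#' @slot areaMm2 numeric, member-pixel count times pixel area, exactly.
#' @slot centroidMm numeric length-2, mean member-pixel centre (mm).
#' @slot pixelSpacing numeric length-2 mm.
#' @slot selectionRule character recording how the component was chosen.
#' @slot sourceId character.
#' @exportClass SafeZone
setClass("SafeZone",
  representation(
    region = "matrix", threshold = "numeric", polygon = "matrix",
    areaMm2 = "numeric", centroidMm = "numeric", pixelSpacing = "numeric",
    selectionRule = "character", sourceId = "character"
  )
)

setValidity("SafeZone", function(object) {
  if (!all(object@region %in% c(0L, 1L))) return("region must be 0/1")
  if (sum(object@region) < 1L) return("region must be non-empty")
  lab <- labelComponents2D(object@region == 1L)
  if (max(lab) != 1L) return("region must be a single 8-connected component")
  a <- sum(object@region) * prod(object@pixelSpacing)
  if (!isTRUE(all.equal(a, object@areaMm2)))
    return("areaMm2 must equal member-pixel count x pixel area")
  TRUE
})

#' DisplayImage: an 8-bit windowed rendering
#'
#' Display product of [windowDisplay()] or [transferOutline()]: either a
#' greyscale matrix or an H x W x 3 RGB array with integer values in
#' 0..255.
#'
#' @slot pixels integer matrix or 3D array, values in 0..255.
#' @slot pixelSpacing numeric length-2 mm.
#' @exportClass DisplayImage
setClass("DisplayImage",
  representation(pixels = "array", pixelSpacing = "numeric")
)

setValidity("DisplayImage", function(object) {
  p <- object@pixels
  nd <- length(dim(p))
  if (!(nd == 2L || (nd == 3L && dim(p)[3] == 3L)))
    return("pixels must be a matrix or an H x W x 3 array")
  if (min(p) < 0 || max(p) > 255) return("pixel values must lie in 0..255")
  TRUE
})

#' PhantomSpec: parameters of the synthetic pelvic CT phantom
#'
#' Describes an ellipsoidal sacral body with a thin cortical shell, an
#' elevated-density S1 core, optional low-density foraminal channels,
#' surrounding soft tissue, additive Gaussian noise and anisotropic voxel
#' spacing. Defaults emulate a low-bone-density elderly pelvic CT at the
#' acquisition geometry the method targets (0.672 mm in-plane, 2.976 mm
#' longitudinal).
#'
#' @slot shape integer length-3 grid dimensions.
#' @slot spacing numeric length-3 mm.
#' @slot bodyCenter,bodySemiaxes numeric length-3 mm: sacral body ellipsoid.
#' @slot shellThickness numeric mm: cortical shell depth inside the body
#'   surface.
#' @slot coreCenter,coreSemiaxes numeric length-3 mm: dense S1 core,
#'   strictly inside the body.
#' @slot foramina list of lists with `center` (length-3 mm), `axis`
#'   (1..3) and `radius` (mm): cylindrical low-density channels.
#' @slot huSoft,huTrabecular,huCortical,huCore,huForamen numeric HU levels;
#'   must satisfy huCortical > huCore > huTrabecular > huSoft >= huForamen.
#' @slot noiseSd numeric >= 0, additive Gaussian noise (HU).
#' @slot seed integer random seed; generation is a pure function of the
#'   spec including this seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    shape = "integer", spacing = "numeric",
    bodyCenter = "numeric", bodySemiaxes = "numeric",
    shellThickness = "numeric",
    coreCenter = "numeric", coreSemiaxes = "numeric",
    foramina = "list",
    huSoft = "numeric", huTrabecular = "numeric", huCortical = "numeric",
    huCore = "numeric", huForamen = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive integers")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (!(object@huCore > object@huTrabecular))
    return("huCore must exceed huTrabecular")
  if (!(object@huTrabecular > object@huSoft))
    return("huTrabecular must exceed huSoft")
  if (!(object@huSoft >= object@huForamen))
    return("huSoft must be >= huForamen")
  if (!(object@huCortical > object@huCore))
    return("huCortical must exceed huCore")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@shellThickness < 0) return("shellThickness must be >= 0")
  if (any(object@coreSemiaxes <= 0) || any(object@bodySemiaxes <= 0))
    return("semi-axes must be positive")
  ## Sufficient containment check: sample the core surface densely and
  ## require every sample strictly inside the body ellipsoid.
  th <- seq(0, pi, length.out = 25)
  ph <- seq(0, 2 * pi, length.out = 49)
  g <- expand.grid(th = th, ph = ph)
  pts <- cbind(
    object@coreCenter[1] + object@coreSemiaxes[1] * sin(g$th) * cos(g$ph),
    object@coreCenter[2] + object@coreSemiaxes[2] * sin(g$th) * sin(g$ph),
    object@coreCenter[3] + object@coreSemiaxes[3] * cos(g$th)
  )
  q <- ((pts[, 1] - object@bodyCenter[1]) / object@bodySemiaxes[1])^2 +
       ((pts[, 2] - object@bodyCenter[2]) / object@bodySemiaxes[2])^2 +
       ((pts[, 3] - object@bodyCenter[3]) / object@bodySemiaxes[3])^2
  if (max(q) >= 1)
    return("core ellipsoid must lie strictly inside the body ellipsoid")
  TRUE
})
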