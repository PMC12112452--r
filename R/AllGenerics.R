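#' Accessor generics
#'
#' Accessors for the imaging containers: `voxelData()` returns the raw 3D
#' array, `spacing()` the per-axis voxel pitch in mm, `origin()` the mm
#' origin, `sourceId()` the dataset identifier, `pixels()` a projection or
#' display raster, `pixelSpacing()` its 2D pitch, `provenance()` whether a
#' projection is masked or full, `summedAxis()` the axis integrated over,
#' `polylines()` the contour vertex lists and `threshold()` the generating
#' level, and `zoneRegion()`, `zonePolygon()`, `zoneArea()`,
#' `zoneCentroid()` the safe-zone components.
#'
#' @param object one of the package's S4 containers.
#' @return the slot value described above.
#' @name accessors
#' @aliases voxelData spacing origin sourceId pixels pixelSpacing
#'   provenance summedAxis polylines threshold zoneRegion zonePolygon
#'   zoneArea zoneCentroid
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("summedAxis", function(object) standardGeneric("summedAxis"))
#' @rdname accessors
#' @export
setGeneric("polylines", function(object) standardGeneric("polylines"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("zoneRegion", function(object) standardGeneric("zoneRegion"))
#' @rdname accessors
#' @export
setGeneric("zonePolygon", function(object) standardGeneric("zonePolygon"))
#' @rdname accessors
#' @export
setGeneric("zoneArea", function(object) standardGeneric("zoneArea"))
#' @rdname accessors
#' @export
setGeneric("zoneCentroid", function(object) standardGeneric("zoneCentroid"))

#' @rdname accessors
setMethod("voxelData", "VoxelVolume", function(object) object@data)
#' @rdname accessors
setMethod("voxelData", "BinaryMask", function(object) object@data)
#' @rdname accessors
setMethod("spacing", "VoxelVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "BinaryMask", function(object) object@spacing)
#' @rdname accessors
setMethod("origin", "VoxelVolume", function(object) object@origin)
#' @rdname accessors
setMethod("origin", "BinaryMask", function(object) object@origin)
#' @rdname accessors
setMethod("sourceId", "VoxelVolume", function(object) object@sourceId)
#' @rdname accessors
setMethod("sourceId", "Projection2D", function(object) object@sourceId)
#' @rdname accessors
setMethod("sourceId", "ContourSet", function(object) object@sourceId)
#' @rdname accessors
setMethod("sourceId", "SafeZone", function(object) object@sourceId)
#' @rdname accessors
setMethod("pixels", "Projection2D", function(object) object@pixels)
#' @rdname accessors
setMethod("pixels", "DisplayImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixelSpacing", "Projection2D", function(object) object@pixelSpacing)
#' @rdname accessors
setMethod("pixelSpacing", "DisplayImage", function(object) object@pixelSpacing)
#' @rdname accessors
setMethod("pixelSpacing", "SafeZone", function(object) object@pixelSpacing)
#' @rdname accessors
setMethod("provenance", "Projection2D", function(object) object@provenance)
#' @rdname accessors
setMethod("summedAxis", "Projection2D", function(object) object@summedAxis)
#' @rdname accessors
setMethod("polylines", "ContourSet", function(object) object@polylines)
#' @rdname accessors
setMethod("threshold", "ContourSet", function(object) object@threshold)
#' @rdname accessors
setMethod("threshold", "SafeZone", function(object) object@threshold)
#' @rdname accessors
setMethod("zoneRegion", "SafeZone", function(object) object@region)
#' @rdname accessors
setMethod("zonePolygon", "SafeZone", function(object) object@polygon)
#' @rdname accessors
setMethod("zoneArea", "SafeZone", function(object) object@areaMm2)
#' @rdname accessors
setMethod("zoneCentroid", "SafeZone", function(object) object@centroidMm)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume %dx%dx%d (RL-AP-IS), spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], source '%s'\n",
              min(object@data), max(object@data), object@sourceId))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask %dx%dx%d, %d member voxels (%.1f cm^3)\n",
              d[1], d[2], d[3], sum(object@data),
              sum(object@data) * prod(object@spacing) / 1000))
})

setMethod("show", "PolygonTraceSet", function(object) {
  cat(sprintf("PolygonTraceSet: %d polygon(s) on axis-%d slices\n",
              length(object@traces), object@sliceAxis))
})

setMethod("show", "Projection2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Projection2D (%s) %dx%d px @ %.3f x %.3f mm, summed over %s\n",
              object@provenance, d[1], d[2], object@pixelSpacing[1],
              object@pixelSpacing[2], object@summedAxis))
  cat(sprintf("  intensity range [%.1f, %.1f] HU.mm, source '%s'\n",
              min(object@pixels), max(object@pixels), object@sourceId))
})

setMethod("show", "ContourSet", function(object) {
  cat(sprintf("ContourSet: %d closed polyline(s) at threshold %.1f HU.mm\n",
              length(object@polylines), object@threshold))
})

setMethod("show", "SafeZone", function(object) {
  cat(sprintf(
    "SafeZone: %.1f mm^2 at threshold %.1f HU.mm, centroid (%.2f, %.2f) mm\n",
    object@areaMm2, object@threshold, object@centroidMm[1],
    object@centroidMm[2]))
  cat(sprintf("  selection: %s\n", object@selectionRule))
})

setMethod("show", "DisplayImage", function(object) {
  d <- dim(object@pixels)
  kind <- if (length(d) == 3L) "RGB" else "greyscale"
  cat(sprintf("DisplayImage (%s) %dx%d px, 8-bit\n", kind, d[1], d[2]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%dx%d @ %.3f/%.3f/%.3f mm, noise sd %.1f HU, seed %d\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@noiseSd, object@seed))
})
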