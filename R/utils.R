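## Internal geometry and grid helpers shared across modules.

## Physical centre coordinates of voxels/pixels along one axis:
## origin + (0-based index + 0.5) * spacing.
axisCenters <- function(n, spacing, origin = 0) {
  origin + (seq_len(n) - 0.5) * spacing
}

## Even-odd point-in-polygon with boundary-touching points counted inside.
## px, py: point coordinate vectors; poly: closed n x 2 matrix. Vectorised
## over points (crossing-number accumulated edge by edge).
pointsInPolygonEO <- function(px, py, poly, boundaryTol = 1e-9) {
  nv <- nrow(poly)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  for (e in seq_len(nv - 1L)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[e + 1L, 1]; y2 <- poly[e + 1L, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
    ## boundary test: distance from point to segment below tolerance
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    } else {
      d2 <- (px - x1)^2 + (py - y1)^2
    }
    onEdge <- onEdge | d2 <= boundaryTol^2
  }
  inside | onEdge
}

## Joint even-odd parity over several polygons (XOR), boundary inclusive.
pointsInPolygonsEO <- function(px, py, polys, boundaryTol = 1e-9) {
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  for (poly in polys) {
    nv <- nrow(poly)
    for (e in seq_len(nv - 1L)) {
      x1 <- poly[e, 1]; y1 <- poly[e, 2]
      x2 <- poly[e + 1L, 1]; y2 <- poly[e + 1L, 2]
      crosses <- ((y1 > py) != (y2 > py))
      if (any(crosses)) {
        xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
        flip <- px[crosses] < xint
        idx <- which(crosses)[flip]
        inside[idx] <- !inside[idx]
      }
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx * dx + dy * dy
      if (L2 > 0) {
        t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
        d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      } else {
        d2 <- (px - x1)^2 + (py - y1)^2
      }
      onEdge <- onEdge | d2 <= boundaryTol^2
    }
  }
  inside | onEdge
}

## Shoelace signed area of a closed polygon (n x 2, first = last row).
polygonArea <- function(poly) {
  n <- nrow(poly)
  x <- poly[-n, 1]; y <- poly[-n, 2]
  x2 <- poly[-1, 1]; y2 <- poly[-1, 2]
  sum(x * y2 - x2 * y) / 2
}

## 8-connected labelling of a 2D logical matrix (via the 3D engine with a
## singleton third axis; 26-connectivity restricted to one slice is
## 8-connectivity).
labelComponents2D <- function(m) {
  stopifnot(is.matrix(m))
  lab <- label_components_cpp(as.logical(m), c(dim(m), 1L), 26L)
  matrix(lab, nrow(m), ncol(m))
}

## Offsets (m x 3 integer) of an ellipsoidal structuring element whose mm
## radius converts per-axis through the voxel spacing.
ellipsoidOffsets <- function(radiusMm, spacing) {
  r <- pmax(0L, as.integer(floor(radiusMm / spacing + 1e-9)))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  if (radiusMm <= 0) {
    keep <- g$dx == 0 & g$dy == 0 & g$dz == 0
  } else {
    keep <- (g$dx * spacing[1] / radiusMm)^2 +
            (g$dy * spacing[2] / radiusMm)^2 +
            (g$dz * spacing[3] / radiusMm)^2 <= 1 + 1e-9
  }
  as.matrix(g[keep, , drop = FALSE])
}

## Map an axis spec ("RL"/"AP"/"IS" or the clinical synonyms lateral/ap/
## axial, or an index 1..3) to the canonical axis index.
resolveAxis <- function(axis) {
  if (is.numeric(axis)) {
    a <- as.integer(axis)
    if (!(a %in% 1:3)) stop("axis index must be 1, 2 or 3")
    return(a)
  }
  key <- tolower(as.character(axis))
  a <- switch(key,
    rl = 1L, lateral = 1L, mediolateral = 1L,
    ap = 2L, anteroposterior = 2L,
    is = 3L, axial = 3L, craniocaudal = 3L,
    stop("unknown axis '", axis, "'"))
  a
}

canonicalAxisLabel <- function(a) CANONICAL_AXES[a]

## Congruence check between a mask and a volume grid.
checkCongruent <- function(mask, volume, spacingTol = 1e-3) {
  if (!identical(dim(mask@data), dim(volume@data)))
    stop("grid mismatch: mask shape (",
         paste(dim(mask@data), collapse = "x"),
         ") differs from volume shape (",
         paste(dim(volume@data), collapse = "x"), ")")
  if (any(abs(mask@spacing - volume@spacing) > spacingTol))
    stop("grid mismatch: mask spacing differs from volume spacing by more ",
         "than ", spacingTol, " mm")
  invisible(TRUE)
}
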