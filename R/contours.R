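## Marching squares with linear interpolation on the pixel-centre grid.
## The field is padded with a value strictly below the level so every
## contour closes, including at image borders. "Inside" means value >=
## level; interpolation fractions are clipped away from 0 and 1 so inside
## grid nodes are strictly enclosed and outside nodes strictly excluded.
## Saddle cells (two inside corners on a diagonal) are resolved toward the
## higher-valued diagonal; since each inside corner is >= level and each
## outside corner is below it, that is always the inside diagonal, which
## makes contour topology agree with 8-connectivity of the super-level
## set.

marchingSquares <- function(m, level, du, dv) {
  nr <- nrow(m); nc <- ncol(m)
  padVal <- min(min(m), level) - 1
  P <- matrix(padVal, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m
  ins <- P >= level
  eps <- 1e-6

  ## mm coordinate of padded node (k, l): centres of original pixels are
  ## at (i - 0.5) * du for 1-based i, so padded index k maps to
  ## (k - 1.5) * du.
  ucoord <- function(k) (k - 1.5) * du
  vcoord <- function(l) (l - 1.5) * dv

  pts <- new.env(hash = TRUE, parent = emptyenv())
  segA <- character(0)
  segB <- character(0)

  isPad <- function(k, l) k == 1L || k == nr + 2L || l == 1L || l == nc + 2L

  crossPoint <- function(k1, l1, k2, l2, key) {
    if (is.null(pts[[key]])) {
      a <- P[k1, l1]; b <- P[k2, l2]
      s <- (level - a) / (b - a)
      ## crossings against a pad node are pinned to the pixel boundary
      ## half of the edge so every vertex stays within the image extent
      lo <- if (isPad(k1, l1)) 0.5 else eps
      hi <- if (isPad(k2, l2)) 0.5 else 1 - eps
      s <- min(max(s, lo), hi)
      pts[[key]] <- c(ucoord(k1) + s * (ucoord(k2) - ucoord(k1)),
                      vcoord(l1) + s * (vcoord(l2) - vcoord(l1)))
    }
    key
  }

  ## edge keys: horizontal edge H:k:l joins nodes (k,l)-(k,l+1);
  ## vertical edge V:k:l joins nodes (k,l)-(k+1,l).
  for (k in seq_len(nr + 1L)) {
    for (l in seq_len(nc + 1L)) {
      b00 <- ins[k, l]; b01 <- ins[k, l + 1L]
      b10 <- ins[k + 1L, l]; b11 <- ins[k + 1L, l + 1L]
      nIn <- b00 + b01 + b10 + b11
      if (nIn == 0L || nIn == 4L) next
      eTop    <- function() crossPoint(k, l, k, l + 1L, sprintf("H:%d:%d", k, l))
      eBottom <- function() crossPoint(k + 1L, l, k + 1L, l + 1L,
                                       sprintf("H:%d:%d", k + 1L, l))
      eLeft   <- function() crossPoint(k, l, k + 1L, l, sprintf("V:%d:%d", k, l))
      eRight  <- function() crossPoint(k, l + 1L, k + 1L, l + 1L,
                                       sprintf("V:%d:%d", k, l + 1L))
      addSeg <- function(ka, kb) {
        segA[length(segA) + 1L] <<- ka
        segB[length(segB) + 1L] <<- kb
      }
      if (nIn == 1L) {
        if (b00) addSeg(eTop(), eLeft())
        else if (b01) addSeg(eTop(), eRight())
        else if (b10) addSeg(eBottom(), eLeft())
        else addSeg(eBottom(), eRight())
      } else if (nIn == 3L) {
        if (!b00) addSeg(eTop(), eLeft())
        else if (!b01) addSeg(eTop(), eRight())
        else if (!b10) addSeg(eBottom(), eLeft())
        else addSeg(eBottom(), eRight())
      } else if ((b00 && b11) || (b01 && b10)) {
        ## saddle: keep the inside (higher-valued) diagonal connected
        if (b00 && b11) {
          addSeg(eTop(), eRight())   # isolates corner (k, l+1)
          addSeg(eBottom(), eLeft()) # isolates corner (k+1, l)
        } else {
          addSeg(eTop(), eLeft())    # isolates corner (k, l)
          addSeg(eBottom(), eRight())# isolates corner (k+1, l+1)
        }
      } else {
        ## two adjacent inside corners: one crossing segment
        if (b00 && b01) addSeg(eLeft(), eRight())
        else if (b10 && b11) addSeg(eLeft(), eRight())
        else if (b00 && b10) addSeg(eTop(), eBottom())
        else addSeg(eTop(), eBottom())
      }
    }
  }

  nSeg <- length(segA)
  if (nSeg == 0L) return(list())

  ## assemble closed loops: each crossing edge touches exactly two segments
  inc <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seq_len(nSeg)) {
    for (key in c(segA[s], segB[s]))
      inc[[key]] <- c(inc[[key]], s)
  }
  used <- logical(nSeg)
  loops <- list()
  for (s0 in seq_len(nSeg)) {
    if (used[s0]) next
    keys <- c(segA[s0], segB[s0])
    used[s0] <- TRUE
    repeat {
      tail <- keys[length(keys)]
      cand <- inc[[tail]]
      nxt <- cand[!used[cand]]
      if (length(nxt) == 0L) break
      s <- nxt[1L]
      used[s] <- TRUE
      keys <- c(keys, if (segA[s] == tail) segB[s] else segA[s])
    }
    verts <- t(vapply(keys, function(k) pts[[k]], numeric(2)))
    rownames(verts) <- NULL
    if (!isTRUE(all.equal(verts[1, ], verts[nrow(verts), ])))
      verts <- rbind(verts, verts[1, ])
    loops[[length(loops) + 1L]] <- verts
  }
  loops
}

#' Extract closed iso-density contours from a projection
#'
#' Sub-pixel iso-lines of the super-level set `{P >= threshold}`,
#' extracted by marching squares with linear interpolation (see the
#' package vignette for the saddle rule). The projection is padded below
#' the threshold before extraction, so all contours are closed even when
#' the super-level set touches the image border. Vertices are in
#' projection mm coordinates.
#'
#' @param projection a [Projection2D-class].
#' @param threshold finite HU·mm level. A threshold above the global
#'   maximum yields an empty contour set (not an error).
#' @return a [ContourSet-class].
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSd = 0))
#' p <- sumProjection(ph$volume, ph$truthMask)
#' cs <- extractContours(p, pickThreshold(p, q = 0.20))
#' length(polylines(cs))
extractContours <- function(projection, threshold) {
  stopifnot(is(projection, "Projection2D"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  loops <- marchingSquares(projection@pixels, threshold,
                           projection@pixelSpacing[1],
                           projection@pixelSpacing[2])
  new("ContourSet", polylines = loops, threshold = threshold,
      sourceId = projection@sourceId)
}
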