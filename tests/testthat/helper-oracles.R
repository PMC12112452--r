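## Independent brute-force oracles. These deliberately re-derive results
## with the plainest possible code (triple loops, per-point ray casting,
## BFS flood fill) and stay independent of the implementation paths they
## check.

## Plain ascending triple-loop summation projection.
bruteProjection <- function(volume, mask = NULL, axis = 1L, clamp = TRUE) {
  arr <- voxelData(volume)
  d <- dim(arr)
  ds <- spacing(volume)[axis]
  inpl <- setdiff(1:3, axis)
  mk <- if (is.null(mask)) NULL else voxelData(mask)
  P <- matrix(0, d[inpl[1]], d[inpl[2]])
  for (i in seq_len(d[inpl[1]])) {
    for (j in seq_len(d[inpl[2]])) {
      s <- 0
      for (k in seq_len(d[axis])) {
        idx <- integer(3)
        idx[axis] <- k
        idx[inpl[1]] <- i
        idx[inpl[2]] <- j
        v <- arr[idx[1], idx[2], idx[3]]
        if (clamp && v < 0) v <- 0
        if (!is.null(mk) && mk[idx[1], idx[2], idx[3]] == 0L) v <- 0
        s <- s + v * ds
      }
      P[i, j] <- s
    }
  }
  P
}

## Crossing-number point-in-polygon (single point, single polygon).
brutePointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  cnt <- 0L
  for (e in seq_len(n - 1L)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[e + 1L, 1]; y2 <- poly[e + 1L, 2]
    if ((y1 > py) != (y2 > py)) {
      xi <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xi) cnt <- cnt + 1L
    }
  }
  cnt %% 2L == 1L
}

## Parity of a point against several polygons jointly.
brutePointInPolygons <- function(px, py, polys) {
  hits <- vapply(polys, function(p) brutePointInPolygon(px, py, p), FALSE)
  sum(hits) %% 2L == 1L
}

## BFS flood fill returning a label array (small grids only).
bruteLabel <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nxt <- 0L
  for (s in which(mask != 0L)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      ci <- (cur - 1L) %% d[1] + 1L
      cj <- ((cur - 1L) %/% d[1]) %% d[2] + 1L
      ck <- (cur - 1L) %/% (d[1] * d[2]) + 1L
      for (m in seq_len(nrow(offs))) {
        i <- ci + offs[m, 1]; j <- cj + offs[m, 2]; k <- ck + offs[m, 3]
        if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) next
        t <- i + d[1] * (j - 1L) + d[1] * d[2] * (k - 1L)
        if (mask[t] != 0L && lab[t] == 0L) {
          lab[t] <- nxt
          queue <- c(queue, t)
        }
      }
    }
  }
  lab
}

## Brute dilation / erosion over explicit offsets (small grids only).
bruteDilate <- function(mask, offs) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (s in which(mask != 0L)) {
    ci <- (s - 1L) %% d[1] + 1L
    cj <- ((s - 1L) %/% d[1]) %% d[2] + 1L
    ck <- (s - 1L) %/% (d[1] * d[2]) + 1L
    for (m in seq_len(nrow(offs))) {
      i <- ci + offs[m, 1]; j <- cj + offs[m, 2]; k <- ck + offs[m, 3]
      if (i >= 1 && j >= 1 && k >= 1 && i <= d[1] && j <= d[2] && k <= d[3])
        out[i, j, k] <- TRUE
    }
  }
  out
}

## A small, fast phantom for unit tests (not the study-scale default).
smallPhantomSpec <- function(noiseSd = 0, seed = 1L) {
  phantomSpec(shape = c(48L, 48L, 24L), spacing = c(1, 1, 2),
              bodyCenter = c(24, 24, 24), bodySemiaxes = c(18, 15, 20),
              shellThickness = 1, coreCenter = c(24, 24, 31),
              coreSemiaxes = c(9, 5.5, 6.5),
              foramina = list(list(center = c(17, 24, 18), axis = 2L,
                                   radius = 2.5),
                              list(center = c(31, 24, 18), axis = 2L,
                                   radius = 2.5)),
              noiseSd = noiseSd, seed = seed)
}

## Random test volume wrapped in the class.
randomVolume <- function(d, spacing = c(1, 1, 1), lo = -500, hi = 1500) {
  VoxelVolume(array(stats::runif(prod(d), lo, hi), d), spacing = spacing,
              sourceId = "random")
}

randomMask <- function(d, spacing = c(1, 1, 1), p = 0.5) {
  m <- array(stats::runif(prod(d)) < p, d)
  if (!any(m)) m[1] <- TRUE
  BinaryMask(m, spacing = spacing)
}

expectedCentroidOfFootprint <- function(fp, pxsp) {
  w <- which(fp == 1L, arr.ind = TRUE)
  c(mean((w[, 1] - 0.5) * pxsp[1]), mean((w[, 2] - 0.5) * pxsp[2]))
}
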