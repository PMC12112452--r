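makeProjection <- function(m, sp = c(1, 1), prov = "masked", id = "p") {
  new("Projection2D", pixels = m, pixelSpacing = sp, summedAxis = "RL",
      provenance = prov, sourceId = id)
}

test_that("quantile threshold follows the nearest-rank rule", {
  set.seed(51)
  vals <- sample(1:100)           # 100 distinct positive pixels
  m <- matrix(c(vals, rep(0, 21)), 11, 11)
  p <- makeProjection(m)
  expect_equal(pickThreshold(p, q = 0), 1)       # minimum positive
  expect_equal(pickThreshold(p, q = 1), 100)     # maximum positive
  expect_equal(pickThreshold(p, q = 0.90), 90)   # 90th order statistic
  expect_equal(pickThreshold(p, q = 0.905), 91)  # ceiling rank
  expect_error(pickThreshold(makeProjection(matrix(0, 3, 3))),
               "no positive pixels")
  expect_error(pickThreshold(p, q = 1.5), "0, 1")
})

test_that("a single bright pixel yields one closed contour around its centre", {
  m <- matrix(0, 7, 7)
  m[4, 3] <- 10
  p <- makeProjection(m, sp = c(0.5, 0.5))
  cs <- extractContours(p, 5)
  expect_length(polylines(cs), 1)
  poly <- polylines(cs)[[1]]
  expect_identical(poly[1, ], poly[nrow(poly), ])
  centre <- c((4 - 0.5) * 0.5, (3 - 0.5) * 0.5)
  expect_true(brutePointInPolygon(centre[1], centre[2], poly))
  ## and no other pixel centre is enclosed
  for (i in 1:7) for (j in 1:7) {
    if (i == 4 && j == 3) next
    expect_false(brutePointInPolygon((i - 0.5) * 0.5, (j - 0.5) * 0.5, poly))
  }
  ## vertices stay within the physical image extent
  expect_true(all(poly[, 1] >= 0 & poly[, 1] <= 7 * 0.5))
  expect_true(all(poly[, 2] >= 0 & poly[, 2] <= 7 * 0.5))
})

test_that("contours above the global maximum are empty, not an error", {
  p <- makeProjection(matrix(runif(25), 5, 5))
  expect_length(polylines(extractContours(p, 2)), 0)
})

test_that("contour enclosure matches super-level-set classification", {
  set.seed(52)
  for (trial in 1:5) {
    nr <- sample(10:28, 1); nc <- sample(10:28, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    m <- (m + m[c(2:nr, nr), ] + m[, c(2:nc, nc)]) / 3  # mild smoothing
    t <- as.numeric(quantile(m, runif(1, 0.3, 0.7)))
    cs <- extractContours(makeProjection(m), t)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      enc <- brutePointInPolygons(i - 0.5, j - 0.5, polylines(cs))
      expect_identical(enc, m[i, j] >= t)
    }
  }
})

test_that("saddle cells resolve toward the higher-valued (inside) diagonal", {
  ## diagonal-inside checkerboard: the two bright pixels stay connected
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  cs <- extractContours(makeProjection(m), 0.6)
  expect_length(polylines(cs), 1)   # one loop containing both centres
  poly <- polylines(cs)[[1]]
  expect_true(brutePointInPolygon(0.5, 0.5, poly))
  expect_true(brutePointInPolygon(1.5, 1.5, poly))
  expect_false(brutePointInPolygon(0.5, 1.5, poly))
  expect_false(brutePointInPolygon(1.5, 0.5, poly))
})

test_that("nested thresholds give nested contours", {
  set.seed(53)
  ## smooth two-bump field
  x <- seq(-2, 2, length.out = 24)
  m <- outer(x, x, function(a, b) exp(-(a^2 + b^2)) +
                                  0.7 * exp(-((a - 1)^2 + (b - 1)^2)))
  p <- makeProjection(m)
  t1 <- 0.3; t2 <- 0.6
  c1 <- polylines(extractContours(p, t1))
  c2 <- polylines(extractContours(p, t2))
  expect_gt(length(c1), 0); expect_gt(length(c2), 0)
  for (inner in c2) {
    mid <- colMeans(inner[-nrow(inner), , drop = FALSE])
    expect_true(any(vapply(c1, function(outer)
      brutePointInPolygon(mid[1], mid[2], outer), FALSE)))
  }
})

test_that("safe-zone delineation recovers the region with exact area", {
  m <- matrix(0, 10, 10)
  m[3:5, 4:6] <- 100   # 9-pixel block
  m[8, 9] <- 100       # smaller separate region
  p <- makeProjection(m, sp = c(0.672, 0.672))
  sz <- delineateSafeZone(p, 50)
  expect_s4_class(sz, "SafeZone")
  expect_equal(sum(zoneRegion(sz)), 9L)
  expect_equal(zoneArea(sz), 9 * 0.672^2)
  expect_equal(zoneCentroid(sz), c(3.5 * 0.672, 4.5 * 0.672))
  ## polygon encloses every member centre and no outsider
  for (i in 1:10) for (j in 1:10) {
    enc <- brutePointInPolygon((i - 0.5) * 0.672, (j - 0.5) * 0.672,
                               zonePolygon(sz))
    expect_identical(enc, zoneRegion(sz)[i, j] == 1L)
  }
})

test_that("safe-zone selection rules and errors behave as stated", {
  m <- matrix(0, 10, 10)
  m[2:3, 2:3] <- 100   # equal-area region, superior-most minimal pixel
  m[7:8, 7:8] <- 100
  p <- makeProjection(m)
  sz <- delineateSafeZone(p, 50)
  expect_equal(zoneRegion(sz)[2, 2], 1L)   # tie-break: smallest row/col
  expect_equal(zoneRegion(sz)[7, 7], 0L)

  seeded <- delineateSafeZone(p, 50, select = "seeded", seedMm = c(7.5, 7.5))
  expect_equal(zoneRegion(seeded)[7, 7], 1L)
  expect_error(delineateSafeZone(p, 50, select = "seeded",
                                 seedMm = c(5, 5)), "NoRegion")

  expect_error(delineateSafeZone(p, max(m) + 1), "NoRegion")
  full <- makeProjection(m, prov = "full")
  expect_error(delineateSafeZone(full, 50), "masked projection")
})

test_that("safe-zone area is non-increasing in the threshold and nested", {
  set.seed(54)
  x <- seq(-2, 2, length.out = 20)
  m <- outer(x, x, function(a, b) 1000 * exp(-(a^2 + b^2)))
  p <- makeProjection(m)
  prev <- NULL
  for (t in c(100, 300, 600, 900)) {
    sz <- delineateSafeZone(p, t)
    if (!is.null(prev)) {
      expect_true(all(zoneRegion(sz) <= prev))
      expect_lt(sum(zoneRegion(sz)), sum(prev))
    }
    prev <- zoneRegion(sz)
  }
})

test_that("overlap metrics satisfy the standard identities", {
  set.seed(55)
  a <- matrix(runif(100) < 0.4, 10, 10)
  expect_equal(diceCoefficient(a, a), 1)
  disjoint <- !a
  expect_equal(jaccardIndex(a, disjoint), 0)
  for (trial in 1:5) {
    b <- matrix(runif(100) < 0.4, 10, 10)
    D <- diceCoefficient(a, b); J <- jaccardIndex(a, b)
    expect_equal(D, 2 * J / (1 + J))
  }
})

test_that("zoneMetrics reports exact area and overlap against a reference", {
  m <- matrix(0, 8, 8); m[2:6, 3] <- 100; m[3:6, 4] <- 100; m[4, 5] <- 100
  p <- makeProjection(m, sp = c(0.672, 0.672))
  sz <- delineateSafeZone(p, 50)
  met <- zoneMetrics(sz, reference = zoneRegion(sz))
  expect_equal(met$nPixels, 10L)
  expect_equal(met$areaMm2, 10 * 0.451584)
  expect_equal(met$dice, 1)
  expect_equal(met$jaccard, 1)
  expect_equal(unname(met$boundingBoxMm["uMin"]), 1 * 0.672)
})

test_that("outline transfer asserts shared provenance and stays in register", {
  spec <- smallPhantomSpec(noiseSd = 0)
  ph <- generatePhantom(spec)
  pM <- sumProjection(ph$volume, ph$truthMask)
  pF <- sumProjection(ph$volume)
  cs <- extractContours(pM, pickThreshold(pM, q = 0.20))
  sz <- delineateSafeZone(pM, pickThreshold(pM, q = 0.90))
  img <- transferOutline(list(cs, sz), pF)
  expect_s4_class(img, "DisplayImage")
  expect_equal(dim(pixels(img)), c(dim(pixels(pF)), 3))

  ## an empty contour set leaves the windowed image unchanged
  emptyCs <- extractContours(pM, max(pixels(pM)) + 1)
  base <- windowDisplay(pF)
  img2 <- transferOutline(emptyCs, pF)
  for (ch in 1:3) expect_equal(pixels(img2)[, , ch], pixels(base))

  ## every drawn vertex maps back to within half a pixel
  du <- pixelSpacing(pF)[1]; dv <- pixelSpacing(pF)[2]
  for (poly in c(polylines(cs), list(zonePolygon(sz)))) {
    i <- pmin(pmax(ceiling(poly[, 1] / du), 1), nrow(pixels(pF)))
    j <- pmin(pmax(ceiling(poly[, 2] / dv), 1), ncol(pixels(pF)))
    expect_true(all(abs((i - 0.5) * du - poly[, 1]) <= 0.5 * du + 1e-9))
    expect_true(all(abs((j - 0.5) * dv - poly[, 2]) <= 0.5 * dv + 1e-9))
  }

  ## mismatched source is rejected
  other <- makeProjection(pixels(pF), sp = pixelSpacing(pF), prov = "full",
                          id = "someone-else")
  expect_error(transferOutline(cs, other), "sourceId mismatch")
})
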