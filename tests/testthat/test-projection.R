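test_that("summation projection equals the brute-force triple loop bit-for-bit", {
  set.seed(41)
  for (trial in 1:10) {
    d <- sample(3:8, 3, replace = TRUE)
    v <- randomVolume(d, spacing = runif(3, 0.5, 3))
    m <- randomMask(d, spacing = spacing(v))
    for (axis in 1:3) {
      for (clamp in c(TRUE, FALSE)) {
        p <- sumProjection(v, m, axis = axis, clampNegative = clamp)
        expect_identical(pixels(p), bruteProjection(v, m, axis, clamp))
        pf <- sumProjection(v, NULL, axis = axis, clampNegative = clamp)
        expect_identical(pixels(pf), bruteProjection(v, NULL, axis, clamp))
      }
    }
  }
})

test_that("single-voxel-thick and column sums follow the HU·mm definition", {
  ## one slice of 500 HU at 2 mm pitch -> every pixel 1000 HU·mm
  v <- VoxelVolume(array(500, c(3, 3, 1)), spacing = c(1, 1, 2))
  p <- sumProjection(v, axis = "IS")
  expect_true(all(pixels(p) == 1000))

  ## column of four 1-HU voxels at 2 mm -> 8 HU·mm
  v2 <- VoxelVolume(array(1, c(1, 1, 4)), spacing = c(1, 1, 2))
  expect_equal(as.vector(pixels(sumProjection(v2, axis = "IS"))), 8)

  ## negative HU clamps to zero contribution when clamping is on
  v3 <- VoxelVolume(array(-1000, c(1, 1, 1)), spacing = c(1, 1, 2))
  expect_equal(as.vector(pixels(sumProjection(v3, axis = "IS"))), 0)
  expect_equal(as.vector(pixels(sumProjection(v3, axis = "IS",
                                              clampNegative = FALSE))),
               -2000)
})

test_that("projection conserves mass and masked never exceeds full", {
  set.seed(42)
  projections <- list()
  for (trial in 1:5) {
    d <- sample(4:9, 3, replace = TRUE)
    v <- randomVolume(d, spacing = runif(3, 0.5, 3))
    m <- randomMask(d, spacing = spacing(v))
    a <- sample(1:3, 1)
    pM <- sumProjection(v, m, axis = a)
    pF <- sumProjection(v, NULL, axis = a)
    ## mass conservation against the voxelwise definition
    w <- pmax(voxelData(v), 0) * voxelData(m) * spacing(v)[a]
    expect_lt(abs(sum(pixels(pM)) - sum(w)) / max(sum(w), 1e-12), 1e-6)
    wF <- pmax(voxelData(v), 0) * spacing(v)[a]
    expect_lt(abs(sum(pixels(pF)) - sum(wF)) / sum(wF), 1e-6)
    ## masked <= full pixelwise under clamping
    expect_true(all(pixels(pM) <= pixels(pF) + 1e-9))
  }
})

test_that("projection commutes with whole-voxel in-plane mask translation", {
  ## on a field constant over the projection plane, shifting the mask by
  ## whole voxels shifts the masked projection identically
  set.seed(43)
  d <- c(6, 9, 8)
  prof <- runif(d[1], 0, 1000)   # varies only along the summed (RL) axis
  v <- VoxelVolume(array(rep(prof, times = d[2] * d[3]), d),
                   spacing = c(1, 1, 2))
  m <- array(FALSE, d); m[, 3:5, 2:4] <- runif(6 * 3 * 3) < 0.6
  if (!any(m)) m[1, 3, 2] <- TRUE
  mShift <- array(FALSE, d)
  mShift[, 3:5 + 2, 2:4 + 3] <- m[, 3:5, 2:4]   # +2 AP, +3 IS
  p1 <- sumProjection(v, BinaryMask(m, spacing(v)), axis = 1)
  p2 <- sumProjection(v, BinaryMask(mShift, spacing(v)), axis = 1)
  expect_identical(pixels(p1)[3:5, 2:4], pixels(p2)[5:7, 5:7])
})

test_that("projection rejects incongruent or empty masks", {
  v <- randomVolume(c(4, 4, 4))
  expect_error(sumProjection(v, randomMask(c(5, 4, 4))), "grid mismatch")
  expect_error(sumProjection(v, BinaryMask(array(0L, c(4, 4, 4)))),
               "empty")
})

test_that("isotropic resampling is identity on already-isotropic input", {
  set.seed(44)
  v <- randomVolume(c(6, 5, 4), spacing = c(1.5, 1.5, 1.5))
  r <- resampleIsotropic(v, 1.5)
  expect_identical(voxelData(r), voxelData(v))
})

test_that("resampling a constant volume stays constant", {
  v <- VoxelVolume(array(123.4, c(6, 6, 4)), spacing = c(0.672, 0.672, 2.976))
  r <- resampleIsotropic(v)
  expect_equal(spacing(r), rep(0.672, 3))
  expect_true(all(abs(voxelData(r) - 123.4) < 1e-9))
})

test_that("trilinear resampling reproduces a linear field exactly (interior)", {
  d <- c(8, 8, 12)
  sp <- c(0.672, 0.672, 2.976)
  a <- 100; b <- 35
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  v <- VoxelVolume(array(rep(a + b * z, each = d[1] * d[2]), d), spacing = sp)
  r <- resampleIsotropic(v, 0.672)
  dOut <- dim(voxelData(r))
  zOut <- (seq_len(dOut[3]) - 0.5) * 0.672
  interior <- zOut >= 0.5 * sp[3] & zOut <= d[3] * sp[3] - 0.5 * sp[3]
  want <- a + b * zOut[interior]
  got <- voxelData(r)[4, 4, interior]
  expect_lt(max(abs(got - want) / abs(want)), 1e-6)
})

test_that("resampling rejects an impossible target", {
  v <- randomVolume(c(4, 4, 4), spacing = c(1, 1, 1))
  expect_error(resampleIsotropic(v, 100), "exceeds every physical extent")
})

test_that("mask resampling stays congruent with volume resampling", {
  spec <- smallPhantomSpec(noiseSd = 0)
  ph <- generatePhantom(spec)
  iso <- resampleIsotropic(ph$volume)
  msk <- resampleMaskIsotropic(ph$truthMask)
  expect_identical(dim(voxelData(iso)), dim(voxelData(msk)))
  expect_equal(spacing(iso), spacing(msk))
  ## volume is approximately conserved by the resampled membership
  v1 <- sum(voxelData(ph$truthMask)) * prod(spacing(ph$truthMask))
  v2 <- sum(voxelData(msk)) * prod(spacing(msk))
  expect_lt(abs(v1 - v2) / v1, 0.05)
})

test_that("display windowing maps level to mid-grey and clips correctly", {
  p <- new("Projection2D",
           pixels = matrix(c(-50, 0, 100, 200, 250, 500), 2, 3),
           pixelSpacing = c(1, 1), summedAxis = "RL",
           provenance = "masked", sourceId = "w")
  img <- windowDisplay(p, window = 200, level = 100)
  px <- pixels(img)
  expect_equal(px[1, 2], 128)      # value 100 at level -> mid-grey
  expect_equal(px[1, 1], 0)        # below floor clips to 0
  expect_equal(px[2, 3], 255)      # above ceiling clips to 255
  expect_error(windowDisplay(p, window = 0, level = 10), "positive")

  ## monotone on random images
  set.seed(45)
  m <- matrix(runif(64, -100, 400), 8, 8)
  p2 <- new("Projection2D", pixels = m, pixelSpacing = c(1, 1),
            summedAxis = "RL", provenance = "full", sourceId = "w")
  out <- pixels(windowDisplay(p2, window = 300, level = 150))
  o <- order(as.vector(m))
  expect_true(all(diff(as.vector(out)[o]) >= 0))
})
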