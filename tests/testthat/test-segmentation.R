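test_that("thresholding keeps exactly the in-range voxels and warns when empty", {
  spec <- smallPhantomSpec(noiseSd = 0)
  ph <- generatePhantom(spec)
  arr <- voxelData(ph$volume)

  m <- thresholdMask(ph$volume, segmentationParams(huLow = 300))
  expect_identical(voxelData(m), array(as.integer(arr >= 300), dim(arr)))
  ## the trabecular interior (150 HU) is excluded: only shell + core remain,
  ## a fragmented, non-solid sacrum
  expect_lt(sum(voxelData(m)), 0.5 * sum(voxelData(ph$truthMask)))
  lab <- bruteLabel(voxelData(m), 26L)
  expect_gt(max(lab), 1L)  # shell and core are disconnected

  everything <- thresholdMask(ph$volume, segmentationParams(huLow = -2000))
  expect_true(all(voxelData(everything) == 1L))

  expect_warning(empty <- thresholdMask(ph$volume,
                                        segmentationParams(huLow = 5000)),
                 "empty mask")
  expect_equal(sum(voxelData(empty)), 0L)
})

test_that("thresholding is monotone in the lower bound", {
  set.seed(31)
  v <- randomVolume(c(10, 10, 6))
  lows <- sort(runif(5, -400, 1400))
  prev <- NULL
  for (lo in lows) {
    m <- suppressWarnings(thresholdMask(v, segmentationParams(huLow = lo)))
    if (!is.null(prev)) expect_true(all(voxelData(m) <= prev))
    prev <- voxelData(m)
  }
})

test_that("largestComponent agrees with brute-force flood fill", {
  set.seed(32)
  for (conn in c(6L, 26L)) {
    for (trial in 1:5) {
      m <- array(stats::runif(8 * 8 * 4) < 0.35, c(8, 8, 4))
      if (!any(m)) m[1] <- TRUE
      mask <- BinaryMask(m, spacing = c(1, 1, 1))
      got <- largestComponent(mask, conn)
      lab <- bruteLabel(array(as.integer(m), dim(m)), conn)
      sizes <- tabulate(lab[lab > 0])
      expect_equal(sum(voxelData(got)), max(sizes))
      ## result is one connected component entirely inside the input
      expect_true(all(voxelData(got) <= as.integer(m)))
      relab <- bruteLabel(voxelData(got), conn)
      expect_equal(max(relab), 1L)
    }
  }
})

test_that("largestComponent applies the stated deterministic tie-break", {
  m <- array(0L, c(10, 4, 2))
  m[6:10, 1, 1] <- 1L  # 5 voxels, but larger first index
  m[2:4, 3, 1] <- 1L; m[2:3, 4, 1] <- 1L  # 5 voxels containing (2,3,1)
  mask <- BinaryMask(m, spacing = c(1, 1, 1))
  got <- largestComponent(mask, 26L)
  expect_equal(sum(voxelData(got)), 5L)
  expect_equal(voxelData(got)[2, 3, 1], 1L)   # lexicographically smaller
  expect_equal(voxelData(got)[6, 1, 1], 0L)

  ## single blob passes through unchanged; empty mask errors
  single <- BinaryMask(array(c(rep(1L, 4), rep(0L, 12)), c(4, 2, 2)))
  expect_identical(voxelData(largestComponent(single, 6L)),
                   voxelData(single))
  expect_error(largestComponent(BinaryMask(array(0L, c(2, 2, 2)))), "empty")
})

test_that("closing fills interior holes, is extensive and idempotent", {
  cube <- array(0L, c(7, 7, 7))
  cube[2:6, 2:6, 2:6] <- 1L
  cube[4, 4, 4] <- 0L
  mask <- BinaryMask(cube, spacing = c(1, 1, 1))

  expect_identical(voxelData(closeMask(mask, 0)), voxelData(mask))

  closed <- closeMask(mask, 1.5)
  expect_equal(voxelData(closed)[4, 4, 4], 1L)            # hole filled
  expect_true(all(voxelData(closed) >= cube))             # extensive
  expect_identical(voxelData(closeMask(closed, 1.5)),
                   voxelData(closed))                     # idempotent

  ## extensivity holds on random blobs, including ones touching borders
  set.seed(33)
  for (trial in 1:4) {
    m <- array(stats::runif(6 * 6 * 6) < 0.3, c(6, 6, 6))
    if (!any(m)) m[1] <- TRUE
    blob <- BinaryMask(m, spacing = c(1, 1.3, 0.8))
    cl <- closeMask(blob, 1.6)
    expect_true(all(voxelData(cl) >= voxelData(blob)))
    expect_identical(voxelData(closeMask(cl, 1.6)), voxelData(cl))
  }
})

test_that("dilation/erosion kernels match the brute-force oracle", {
  set.seed(34)
  offs <- sacrozone:::ellipsoidOffsets(1.5, c(1, 1, 1))
  m <- array(stats::runif(6 * 6 * 6) < 0.3, c(6, 6, 6))
  got <- sacrozone:::binary_dilate_cpp(as.logical(m), dim(m), offs)
  expect_identical(array(got, dim(m)), bruteDilate(m, offs))
})

test_that("segmentation parameter validation", {
  expect_error(segmentationParams(huLow = 500, huHigh = 100), "below")
  expect_error(segmentationParams(huLow = 0, connectivity = 18), "6 or 26")
  expect_error(segmentationParams(huLow = 0, closingRadiusMm = -1), ">= 0")
})
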