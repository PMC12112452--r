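test_that("zero-noise phantom assigns the stated HU by region", {
  spec <- smallPhantomSpec(noiseSd = 0)
  ph <- generatePhantom(spec)
  arr <- voxelData(ph$volume)
  sp <- spec@spacing
  at <- function(mm) {
    idx <- pmax(1L, as.integer(floor(mm / sp)) + 1L)
    arr[idx[1], idx[2], idx[3]]
  }
  expect_equal(at(spec@coreCenter), 400)        # core centre
  expect_equal(arr[1, 1, 1], 40)                # soft tissue corner
  expect_equal(at(spec@bodyCenter - c(0, 0, 10)), 150)  # trabecular interior
  expect_equal(at(spec@foramina[[1]]$center), 20)  # foraminal channel
})

test_that("truth mask volume matches the analytic ellipsoid volume", {
  ## semi-axes are >= 10 voxels in-plane at the default grid
  spec <- phantomSpec(noiseSd = 0)
  ph <- generatePhantom(spec)
  vox <- sum(voxelData(ph$truthMask)) * prod(spec@spacing)
  analytic <- 4 / 3 * pi * prod(spec@bodySemiaxes)
  expect_lt(abs(vox - analytic) / analytic, 0.05)
  coreVox <- sum(voxelData(ph$truthCore)) * prod(spec@spacing)
  coreAnalytic <- 4 / 3 * pi * prod(spec@coreSemiaxes)
  expect_lt(abs(coreVox - coreAnalytic) / coreAnalytic, 0.05)
})

test_that("phantom generation is a pure function of the spec", {
  a <- generatePhantom(smallPhantomSpec(noiseSd = 15, seed = 7))
  b <- generatePhantom(smallPhantomSpec(noiseSd = 15, seed = 7))
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(voxelData(a$truthMask), voxelData(b$truthMask))
  c <- generatePhantom(smallPhantomSpec(noiseSd = 15, seed = 8))
  expect_false(identical(voxelData(a$volume), voxelData(c$volume)))
  ## generation must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generatePhantom(smallPhantomSpec(noiseSd = 15)))
  expect_identical(rnorm(3), before)
})

test_that("noise-free masked projection peaks on a core ray", {
  spec <- smallPhantomSpec(noiseSd = 0)
  ph <- generatePhantom(spec)
  p <- sumProjection(ph$volume, ph$truthMask, axis = "RL")
  fp <- coreFootprint(spec, p)
  peak <- which(pixels(p) == max(pixels(p)), arr.ind = TRUE)[1, ]
  expect_equal(fp[peak[1], peak[2]], 1L)
})

test_that("spec validity rejects impossible phantoms", {
  expect_error(phantomSpec(coreCenter = c(200, 200, 200)),
               "inside the body")
  expect_error(phantomSpec(huCore = 100),    # core below trabecular
               "huCore")
  expect_error(phantomSpec(noiseSd = -1), "noiseSd")
})

test_that("phantom spec JSON round-trips", {
  spec <- smallPhantomSpec(noiseSd = 5, seed = 3L)
  f <- tempfile(fileext = ".json")
  writePhantomSpec(spec, f)
  spec2 <- readPhantomSpec(f)
  expect_equal(spec2@shape, spec@shape)
  expect_equal(spec2@spacing, spec@spacing)
  expect_equal(spec2@coreCenter, spec@coreCenter)
  expect_equal(spec2@noiseSd, spec@noiseSd)
  expect_equal(spec2@seed, spec@seed)
  expect_identical(voxelData(generatePhantom(spec2)$volume),
                   voxelData(generatePhantom(spec)$volume))
})

test_that("phantom traces recover the truth mask almost exactly", {
  spec <- smallPhantomSpec(noiseSd = 0)
  ph <- generatePhantom(spec)
  m <- rasterizeTraces(phantomTraces(spec), ph$volume)
  truth <- voxelData(ph$truthMask)
  recovered <- sum(voxelData(m) & truth) / sum(truth)
  expect_gte(recovered, 0.99)
})
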