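test_that("encoding is deterministic, linear-headed and shape-checked", {
  st <- untrainedStack()
  vol <- array(rnorm(512), dim = c(8, 8, 8))
  w <- encodeVolume(st$enc, vol)
  expect_length(w, 6L)
  expect_identical(w, encodeVolume(st$enc, vol))
  expect_error(encodeVolume(st$enc, array(0, c(4, 4, 4))), "expects")
  # the head is affine: encode(a x) - encode(0) is homogeneous in a
  z <- encodeVolume(st$enc, array(0, c(8, 8, 8)))
  w2 <- encodeVolume(st$enc, 2 * vol)
  # LReLU breaks global linearity, so only check the head is not saturated
  expect_false(all(w2 == w))
})

test_that("paper-default architecture: five blocks, 16/32/32/32/16 depths, 96 linear head", {
  cfg <- encoderConfig()
  expect_equal(encoderFilterDepths(cfg), c(16L, 32L, 32L, 32L, 16L))
  enc <- initEncoder(cfg)
  expect_length(enc@params$convs, 5L)
  dims <- vapply(enc@params$convs, function(l) ncol(l$W), integer(1))
  expect_equal(dims, c(16L, 32L, 32L, 32L, 16L))
  # every block kernel covers a 3 x 3 x 3 neighbourhood
  cins <- c(1L, 16L, 32L, 32L, 32L)
  expect_equal(vapply(enc@params$convs, function(l) nrow(l$W), integer(1)),
               27L * cins)
  # linear dense head of size 96 (no activation applied after it)
  expect_equal(ncol(enc@params$dense$W), 96L)
  expect_length(enc@params$dense$b, 96L)
})

test_that("block count shrinks automatically for grids that cannot be halved five times", {
  expect_warning(cfg <- encoderConfig(inputShape = c(16L, 16L, 16L),
                                      wDim = 16L),
                 "4 downsampling blocks")
  expect_equal(encoderFilterDepths(cfg), c(16L, 32L, 32L, 32L))
})

test_that("encoder training is seeded, improves from zero steps and freezes the generator", {
  AmyloidDyn:::withSeed(4, {
    st <- untrainedStack()
    vols <- lapply(1:8, function(i) synthesize(st$gan, rnorm(6)) +
                     array(rnorm(512, sd = 0.01), c(8, 8, 8)))
    cfg0 <- suppressWarnings(encoderConfig(inputShape = c(8L, 8L, 8L),
                                           filterDepths = c(6L, 6L, 4L),
                                           wDim = 6L, steps = 0L, seed = 5L))
    r0 <- trainEncoder(vols, st$gan, cfg0)
    expect_identical(r0$model@params, initEncoder(cfg0)@params)
    ganBefore <- AmyloidDyn:::flattenParams(st$gan@params)
    cfg <- suppressWarnings(encoderConfig(inputShape = c(8L, 8L, 8L),
                                          filterDepths = c(6L, 6L, 4L),
                                          wDim = 6L, steps = 8L,
                                          batchSize = 2L, seed = 5L))
    r1 <- trainEncoder(vols, st$gan, cfg)
    r2 <- trainEncoder(vols, st$gan, cfg)
    expect_identical(r1$model@params, r2$model@params)
    expect_true(all(is.finite(r1$log$loss)))
    # generator parameters are untouched by encoder training
    expect_identical(AmyloidDyn:::flattenParams(st$gan@params), ganBefore)
    # dimension mismatches are configuration errors
    bad <- suppressWarnings(encoderConfig(inputShape = c(8L, 8L, 8L),
                                          filterDepths = c(6L, 6L, 4L),
                                          wDim = 5L, steps = 1L))
    expect_error(trainEncoder(vols, st$gan, bad), "wDim")
  })
})

test_that("reconstruction preserves shape and normalization rescales the reference region", {
  st <- untrainedStack()
  vol <- array(rnorm(512, mean = 1), dim = c(8, 8, 8))
  rec <- reconstructVolume(vol, st$enc, st$gan)
  expect_equal(dim(rec), dim(vol))
  mask <- array(FALSE, c(8, 8, 8)); mask[1:2, 1:2, 1:2] <- TRUE
  nv <- normalizeVolume(vol, mask)
  expect_equal(mean(nv[mask]), 1.0, tolerance = 1e-12)
  expect_error(normalizeVolume(array(0, c(8, 8, 8)), mask), "reference")
})
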