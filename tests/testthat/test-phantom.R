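test_that("noiseless phantoms encode the affine load-to-SUVR map exactly", {
  spec <- tinySpec(noiseSigma = 0)
  dyn <- groundTruthDynamics(suvrOffset = 1.0, suvrSlope = 1.0)
  masks <- phantomMasks(spec)
  # zero-load ratio is the offset itself
  v0 <- buildPhantom(spec, 0, dyn, seed = 1)
  expect_equal(computeReferenceSuvr(v0, masks), 1.0, tolerance = 1e-12)
  v5 <- buildPhantom(spec, 0.5, dyn, seed = 1)
  expect_equal(computeReferenceSuvr(v5, masks), 1.5, tolerance = 1e-12)
  # identity property across the load range
  for (load in seq(0, 1, by = 0.2)) {
    v <- buildPhantom(spec, load, dyn, seed = 2)
    expect_lt(abs(computeReferenceSuvr(v, masks) - trueSuvr(dyn, load)),
              1e-10)
  }
})

test_that("phantom construction is deterministic and geometry errors name the region", {
  spec <- tinySpec()
  a <- buildPhantom(spec, 0.3, seed = 5)
  b <- buildPhantom(spec, 0.3, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, buildPhantom(spec, 0.3, seed = 6)))
  expect_error(
    phantomSpec(gridShape = c(16, 16, 16),
                cerebellumCenter = c(8, 8, 1), cerebellumRadius = c(8, 8, 4)),
    "cerebellum")
  expect_error(buildPhantom(spec, 2), "aMax")
})

test_that("region masks are disjoint and the SUVR oracle follows hand arithmetic", {
  spec <- tinySpec()
  masks <- phantomMasks(spec)
  expect_true(any(masks$cortex) && any(masks$reference))
  expect_false(any(masks$cortex & masks$reference))
  expect_false(any(masks$cortex & masks$ventricles))
  expect_false(any(masks$reference & masks$ventricles))
  # uniform volume has unit ratio
  u <- array(3.7, dim = c(16, 16, 16))
  expect_equal(computeReferenceSuvr(u, masks), 1.0, tolerance = 1e-12)
  # hand-made 4^3 masks: cortex of 2s over reference of 1s
  vol <- array(0, dim = c(4, 4, 4))
  cortex <- array(FALSE, dim = c(4, 4, 4)); cortex[1:2, , ] <- TRUE
  reference <- array(FALSE, dim = c(4, 4, 4)); reference[3:4, , ] <- TRUE
  vol[cortex] <- 2; vol[reference] <- 1
  expect_equal(computeReferenceSuvr(vol, list(cortex = cortex,
                                              reference = reference)), 2.0)
  empty <- array(FALSE, dim = c(4, 4, 4))
  expect_error(computeReferenceSuvr(vol, list(cortex = empty,
                                              reference = reference)),
               "cortex")
  zero <- array(0, dim = c(4, 4, 4))
  expect_error(computeReferenceSuvr(zero, list(cortex = cortex,
                                               reference = reference)),
               "reference")
})

test_that("the reference integrator matches the logistic closed form", {
  tr <- AmyloidDyn:::.referenceLoadTrajectory(0.1, 0.5, 1, c(0, 4))
  expect_equal(tr[2], 1 / (1 + (1 / 0.1 - 1) * exp(-0.5 * 4)),
               tolerance = 1e-7)
  expect_equal(tr[1], 0.1)
})

test_that("cohort simulation honours schedules, frozen dynamics and reproducibility", {
  spec <- tinySpec()
  # exactly 2 visits per subject -> 20 scan rows for 10 subjects
  sim <- simulateCohort(10, groundTruthDynamics(), spec,
                        visitCountProbs = c(0, 1, 0, 0),
                        writeVolumes = FALSE, seed = 3)
  expect_equal(nrow(sim$cohort), 20L)
  expect_equal(unname(table(sim$cohort$subject_id)), rep(2L, 10),
               ignore_attr = TRUE)
  # r = 0 freezes load and SUVR within subject
  frozen <- simulateCohort(6, groundTruthDynamics(baseRate = 0), spec,
                           writeVolumes = FALSE, seed = 4)
  spread <- tapply(frozen$cohort$suvr, frozen$cohort$subject_id,
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
  # nondecreasing SUVR whenever r >= 0
  sim2 <- simulateCohort(12, groundTruthDynamics(), spec,
                         writeVolumes = FALSE, seed = 5)
  inc <- tapply(seq_len(nrow(sim2$cohort)), sim2$cohort$subject_id,
                function(i) all(diff(sim2$cohort$suvr[i]) >= -1e-12))
  expect_true(all(unlist(inc)))
  # byte-reproducibility of written artifacts
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  simulateCohort(4, spec = spec, outDir = d1, seed = 11)
  simulateCohort(4, spec = spec, outDir = d2, seed = 11)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
  # scan times strictly increase within subject
  coh <- read.csv(file.path(d1, "cohort.csv"))
  ok <- tapply(coh$scan_time_years, coh$subject_id,
               function(t) all(diff(t) > 0) || length(t) == 1L)
  expect_true(all(unlist(ok)))
})
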