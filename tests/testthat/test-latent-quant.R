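test_that("PCA models are orthonormal, sign-fixed and honour rank limits", {
  withSeed(10, {
    # rank-1 data: a single direction explains everything
    u <- rnorm(6); u <- u / sqrt(sum(u^2))
    X1 <- outer(rnorm(30), u) + matrix(rep(rnorm(6), each = 30), 30)
    p1 <- fitPca(X1, 1L)
    expect_equal(p1@varFractions, 1.0, tolerance = 1e-10)
    # full-rank round trip is the identity
    X <- matrix(rnorm(50 * 7), 50, 7)
    pf <- fitPca(X, 7L)
    expect_lt(max(abs(backProject(pf, projectScores(pf, X)) - X)), 1e-8)
    # orthonormality and the positive-largest-coordinate sign convention
    V <- pf@components
    expect_lt(max(abs(crossprod(V) - diag(7))), 1e-10)
    for (k in 1:7) expect_gt(V[which.max(abs(V[, k])), k], 0)
    expect_error(fitPca(X, 8L), "L")
    expect_error(fitPca(X1, 3L), "rank")
  })
})

test_that("projection identities hold: centring, inversion, idempotence", {
  st <- untrainedStack()
  pca <- st$pca
  expect_equal(projectScores(pca, pca@center), numeric(pca@K),
               tolerance = 1e-12)
  expect_equal(backProject(pca, numeric(pca@K)), pca@center,
               tolerance = 1e-12)
  withSeed(11, {
    for (i in 1:5) {
      b <- rnorm(pca@K)
      expect_equal(projectScores(pca, backProject(pca, b)), b,
                   tolerance = 1e-10)
    }
  })
  expect_error(projectScores(pca, rnorm(3)), "dimension")
  expect_error(backProject(pca, rnorm(7)), "dimension")
})

test_that("SUVR regression is exact on affine data and minimum-norm when degenerate", {
  pl <- plantedLatents(n = 80L, L = 6L, sigma = 0)
  fit <- fitSuvrRegression(pl$W, pl$suvr)
  expect_lt(sqrt(mean((predictSuvr(fit, pl$W) - pl$suvr)^2)), 1e-8)
  expect_equal(fit@weights, c(0.4, -0.25, numeric(4)), tolerance = 1e-8)
  # constant target: zero weights, intercept equal to the constant
  cfit <- fitSuvrRegression(pl$W, rep(1.3, 80L))
  expect_equal(cfit@weights, numeric(6), tolerance = 1e-8)
  expect_equal(cfit@intercept, 1.3, tolerance = 1e-10)
  # duplicated column: warning + minimum-norm solution splits the weight
  W2 <- cbind(pl$W[, 1], pl$W[, 1])
  y2 <- pl$W[, 1] * 1.0
  expect_warning(f2 <- fitSuvrRegression(W2, y2), "minimum-norm")
  expect_equal(f2@weights, c(0.5, 0.5), tolerance = 1e-8)
  expect_error(predictSuvr(fit, matrix(rnorm(10), 2)), "dimension")
})

test_that("noisy-slope recovery stays within three standard errors", {
  withSeed(12, {
    n <- 200L
    load <- runif(n)
    x <- load + rnorm(n, sd = 0.05)
    suvr <- 1.0 + 1.0 * load + rnorm(n, sd = 0.02)
    fit <- fitSuvrRegression(matrix(x, ncol = 1), suvr)
    ols <- summary(lm(suvr ~ x))$coefficients   # independent oracle
    expect_equal(fit@weights, ols["x", "Estimate"], tolerance = 1e-8)
    expect_lt(abs(fit@weights - 1.0), 3 * ols["x", "Std. Error"] +
                0.05 * 3) # attenuation from noise-in-x bounded separately
  })
})

test_that("bootstrap evaluation is deterministic, separable when noiseless, and subject-blocked", {
  pl <- plantedLatents(n = 90L, L = 4L, sigma = 0)
  subjects <- rep(sprintf("S%02d", 1:30), each = 3L)
  r1 <- bootstrapEvaluate(pl$W, pl$suvr, subjects, nSplits = 50L, seed = 21L)
  r2 <- bootstrapEvaluate(pl$W, pl$suvr, subjects, nSplits = 50L, seed = 21L)
  expect_identical(r1@splits, r2@splits)
  expect_lt(reportMetric(r1, "rmse")["mean"], 1e-8)
  expect_equal(unname(reportMetric(r1, "auroc")["mean"]), 1.0)
  s <- r1@summary
  expect_true(all(s$lower <= s$mean + 1e-12 & s$mean <= s$upper + 1e-12))
})

test_that("bootstrap CIs shrink with more splits and AUROC ignores monotone transforms", {
  pl <- plantedLatents(n = 60L, L = 3L, sigma = 0.05)
  rSmall <- bootstrapEvaluate(pl$W, pl$suvr, nSplits = 100L, seed = 5L)
  rBig <- bootstrapEvaluate(pl$W, pl$suvr, nSplits = 1000L, seed = 5L)
  wSmall <- diff(unname(reportMetric(rSmall, "rmse")[c("lower", "upper")]))
  wBig <- diff(unname(reportMetric(rBig, "rmse")[c("lower", "upper")]))
  expect_lte(wBig, wSmall * 1.05)
  withSeed(6, {
    labels <- runif(40) > 0.5
    scores <- rnorm(40)
    a1 <- AmyloidDyn:::.aurocOf(labels, scores)
    a2 <- AmyloidDyn:::.aurocOf(labels, exp(2 * scores) - 1)
    expect_equal(a1, a2)
  })
  # single-class splits are excluded and counted
  one <- bootstrapEvaluate(pl$W, rep(1.0, 60), nSplits = 5L, seed = 1L,
                           positivityThreshold = 1.1)
  expect_equal(one@config$aurocMissing, 5L)
})

test_that("elbow curve flattens once the planted signal dimensions are included", {
  withSeed(30, {
    n <- 120L; L <- 6L
    # latent variance concentrated on the first two rotated directions,
    # and SUVR depends only on those two
    scoresTrue <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 2),
                        matrix(rnorm(n * (L - 2), sd = 1e-3), n))
    Q <- qr.Q(qr(matrix(rnorm(L * L), L)))
    W <- scoresTrue %*% t(Q)
    suvr <- 1.2 + 0.3 * scoresTrue[, 1] - 0.2 * scoresTrue[, 2]
    curve <- elbowCurve(W, suvr, Ks = 1:4, nSplits = 30L, seed = 2L)
    expect_equal(curve$K, 1:4)
    # flat and essentially zero from K = 2 on; monotone nonincreasing
    expect_gt(curve$rmse_mean[1], 0.1)
    expect_lt(max(curve$rmse_mean[2:4]), 1e-6)
    expect_true(all(diff(curve$rmse_mean) <= 1e-8))
  })
})

test_that("full-rank elbow entry agrees with the full-latent bootstrap", {
  pl <- plantedLatents(n = 75L, L = 4L, sigma = 0.04)
  curve <- elbowCurve(pl$W, pl$suvr, Ks = c(2L, 4L), nSplits = 60L,
                      seed = 9L)
  full <- bootstrapEvaluate(pl$W, pl$suvr, nSplits = 60L, seed = 9L)
  m <- reportMetric(full, "rmse")
  # CI overlap between the K = L entry and the unprojected bootstrap
  expect_lt(curve$rmse_lower[2], m["upper"])
  expect_gt(curve$rmse_upper[2], m["lower"])
})
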