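makeScores <- function(counts, seed = 1L) {
  # longitudinal score table with the given per-subject scan counts
  AmyloidDyn:::withSeed(seed, {
    rows <- lapply(seq_along(counts), function(i) {
      n <- counts[i]
      t <- cumsum(c(0, runif(max(n - 1L, 0), 0.8, 1.2)))[seq_len(n)]
      data.frame(subject_id = sprintf("S%02d", i), scan_time_years = t,
                 age = 70 + i + t, apoe4_count = (i %% 3L),
                 b1 = rnorm(n), b2 = rnorm(n))
    })
    do.call(rbind, rows)
  })
}

test_that("finite differences follow hand arithmetic and midpoint placement", {
  df <- data.frame(subject_id = "A", scan_time_years = c(0, 0.5),
                   age = c(70, 70.5), apoe4_count = 1L,
                   b1 = c(1, 2), b2 = c(0, 2))
  v <- finiteDifferenceVelocities(df)
  expect_equal(nrow(v), 1L)
  expect_equal(c(v$v_b1, v$v_b2), c(2, 4))
  expect_equal(c(v$b1, v$b2), c(1.5, 1))
  expect_equal(v$age, 70.25)
  expect_equal(v$dt, 0.5)
  vs <- finiteDifferenceVelocities(df, evaluation = "start")
  expect_equal(c(vs$b1, vs$b2), c(1, 0))
  expect_equal(vs$age, 70)
  # identical consecutive latents give zero velocity
  df2 <- df; df2$b1 <- 1; df2$b2 <- 3
  v2 <- finiteDifferenceVelocities(df2)
  expect_equal(c(v2$v_b1, v2$v_b2), c(0, 0))
})

test_that("observation count matches the brute-force pairing oracle", {
  counts <- c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L)
  df <- makeScores(counts)
  v <- finiteDifferenceVelocities(df, minDt = 0.25)
  # brute-force oracle: enumerate consecutive same-subject pairs
  oracle <- 0L
  for (sid in unique(df$subject_id)) {
    t <- sort(df$scan_time_years[df$subject_id == sid])
    if (length(t) >= 2L)
      oracle <- oracle + sum(diff(t) >= 0.25)
  }
  expect_equal(nrow(v), oracle)
  expect_equal(nrow(v), sum(counts - 1L))   # no short gaps in this fixture
  # short-interval pairs are skipped and counted
  dfShort <- rbind(df, data.frame(subject_id = "S01",
                                  scan_time_years = 0.05, age = 71.05,
                                  apoe4_count = 1L, b1 = 0, b2 = 0))
  expect_message(vS <- finiteDifferenceVelocities(dfShort, minDt = 0.25),
                 "skipped")
  expect_equal(attr(vS, "skipped"), 1L)
  expect_equal(nrow(vS), oracle)
  # duplicate timestamps are an error naming the offender
  dfDup <- rbind(df, df[df$subject_id == "S02", ][1L, ])
  expect_error(finiteDifferenceVelocities(dfDup), "S02")
})

test_that("a null velocity field is learned as (almost) zero", {
  df <- makeScores(rep(3L, 10), seed = 4L)
  # freeze each subject's scores over time: observed velocities all zero
  for (sid in unique(df$subject_id)) {
    i <- df$subject_id == sid
    df$b1[i] <- df$b1[i][1]; df$b2[i] <- df$b2[i][1]
  }
  v <- finiteDifferenceVelocities(df)
  field <- fitVelocityField(v, restarts = 2L, seed = 1L)
  at <- as.matrix(v[, c("b1", "b2")])
  pred <- predictVelocity(field, at, v[, c("age", "apoe4_count")])
  expect_lt(max(abs(pred$mean)), 1e-3)
})

test_that("GP posterior interpolates exact data and reverts to the prior far away", {
  ns <- asNamespace("AmyloidDyn")
  AmyloidDyn:::withSeed(5, {
    X <- matrix(runif(30 * 2, -1, 1), 30, 2)
    y <- X[, 1] - 0.5 * X[, 2]
    # zero-noise-limit construction with known hyperparameters (kernel
    # recomputed here directly as the independent oracle)
    sf2 <- 1.5; ls <- c(1.2, 0.8); sn2 <- 1e-10
    K <- sf2 * exp(-0.5 * (outer(X[, 1], X[, 1], "-")^2 / ls[1]^2 +
                           outer(X[, 2], X[, 2], "-")^2 / ls[2]^2))
    diag(K) <- diag(K) + sn2 + 1e-12
    R <- chol(K)
    gp <- list(X = X, y = y, sf2 = sf2, ls = ls, sn2 = sn2, R = R,
               alpha = backsolve(R, backsolve(R, y, transpose = TRUE)))
    pr <- ns$gpPredict(gp, X)
    expect_lt(max(abs(pr$mean - y)), 1e-6)
    near <- ns$gpPredict(gp, c(0, 0))
    far <- ns$gpPredict(gp, c(50, 50))
    expect_lt(abs(far$mean), 1e-6)          # prior mean is zero
    expect_gt(far$var, near$var)
    expect_equal(far$var, sf2, tolerance = 1e-6)
  })
})

test_that("GP posterior mean agrees with kernlab at matched hyperparameters", {
  skip_if_not_installed("kernlab")
  ns <- asNamespace("AmyloidDyn")
  AmyloidDyn:::withSeed(17, {
    X <- matrix(runif(40 * 2, -1, 1), 40, 2)
    y <- sin(2 * X[, 1]) + 0.3 * X[, 2]
    sigmaK <- 0.7                       # kernlab rbfdot parameter
    noise <- 0.01
    ls <- rep(sqrt(1 / (2 * sigmaK)), 2)
    K <- exp(-0.5 * (outer(X[, 1], X[, 1], "-")^2 / ls[1]^2 +
                     outer(X[, 2], X[, 2], "-")^2 / ls[2]^2))
    diag(K) <- diag(K) + noise
    R <- chol(K)
    gp <- list(X = X, y = y, sf2 = 1, ls = ls, sn2 = noise, R = R,
               alpha = backsolve(R, backsolve(R, y, transpose = TRUE)))
    Xs <- matrix(runif(10 * 2, -1, 1), 10, 2)
    ours <- ns$gpPredict(gp, Xs)$mean
    fit <- kernlab::gausspr(X, y, kernel = "rbfdot",
                            kpar = list(sigma = sigmaK), var = noise,
                            scaled = FALSE)
    theirs <- as.numeric(kernlab::predict(fit, Xs))
    expect_equal(ours, theirs, tolerance = 1e-6)
  })
})

test_that("a known linear field is recovered by the GP and its hyperfit is seeded", {
  A <- matrix(c(-0.4, 0.15, 0.1, -0.3), 2, 2)
  obs <- linearFieldObservations(A, n = 120L, sigma = 0.01)
  f1 <- fitVelocityField(obs, restarts = 2L, seed = 3L)
  f2 <- fitVelocityField(obs, restarts = 2L, seed = 3L)
  expect_identical(f1@gps[[1]]$ls, f2@gps[[1]]$ls)
  expect_identical(f1@gps[[2]]$sn2, f2@gps[[2]]$sn2)
  pr <- predictVelocity(f1, c(1, 1), c(age = 75, apoe4_count = 1))
  expect_equal(pr$mean, as.numeric(A %*% c(1, 1)), tolerance = 0.05)
})

test_that("velocity-field recovery sharpens with more observations", {
  A <- matrix(c(-0.4, 0.15, 0.1, -0.3), 2, 2)
  expm4 <- expmEigen(A, 4)
  starts <- rbind(c(0.5, 0.5), c(-0.5, 0.3), c(0.2, -0.6))
  endpointRmse <- function(n) {
    obs <- linearFieldObservations(A, n = n, sigma = 0.05, seed = 31L)
    field <- fitVelocityField(obs, restarts = 2L, seed = 31L)
    errs <- vapply(seq_len(nrow(starts)), function(i) {
      tr <- integrateTrajectory(starts[i, ], c(age = 75, apoe4_count = 1),
                                4, h = 0.01, model = field)
      sum((tr@states[nrow(tr@states), ] -
           as.numeric(expm4 %*% starts[i, ]))^2)
    }, numeric(1))
    sqrt(mean(errs))
  }
  expect_lt(endpointRmse(200L), endpointRmse(50L))
})

test_that("forward Euler matches the closed-form exponential and is first order", {
  decay <- function(b, cv) -b
  tr <- integrateTrajectory(1, c(age = 70), 1, h = 1e-4, model = decay)
  err1 <- abs(tr@states[nrow(tr@states), 1] - exp(-1))
  expect_lt(err1, 1e-3)
  tr2 <- integrateTrajectory(1, c(age = 70), 1, h = 5e-5, model = decay)
  err2 <- abs(tr2@states[nrow(tr2@states), 1] - exp(-1))
  expect_gt(err1 / err2, 1.7)
  expect_lt(err1 / err2, 2.3)
  # duration 0 trajectory is just the initial state
  tr0 <- integrateTrajectory(c(1, 2), c(age = 70), 0, h = 0.1, model = decay)
  expect_equal(nrow(tr0@states), 1L)
  expect_identical(tr0@states[1, ], c(1, 2))
  # non-finite states abort with the step index
  blow <- function(b, cv) b^3 * 1e200
  expect_error(integrateTrajectory(1, c(age = 70), 2, h = 0.5, model = blow),
               "step")
})

test_that("the age covariate advances with integration time", {
  seen <- new.env(); seen$ages <- numeric()
  probe <- function(b, cv) {
    seen$ages <- c(seen$ages, unname(cv["age"]))
    0 * b
  }
  invisible(integrateTrajectory(0, c(age = 70), 1, h = 0.25, model = probe))
  expect_equal(seen$ages, c(70, 70.25, 70.5, 70.75))
})

test_that("image trajectories start bit-identically at the encoded baseline", {
  st <- untrainedStack()
  vol <- array(rnorm(512), dim = c(8, 8, 8))
  still <- function(b, cv) 0 * b
  traj <- generateImageTrajectory(vol, c(age = 70, apoe4_count = 0),
                                  times = c(0, 2), st$enc, st$gan, st$pca,
                                  still, h = 0.5)
  ref <- synthesize(st$gan,
                    backProject(st$pca,
                                projectScores(st$pca,
                                              encodeVolume(st$enc, vol))))
  expect_identical(traj$volumes[[1]], ref)
  expect_equal(dim(traj$volumes[[2]]), c(8L, 8L, 8L))
  expect_equal(traj$differences[[1]], array(0, c(8, 8, 8)))
  # a frozen field keeps the rendering constant
  expect_equal(traj$volumes[[2]], traj$volumes[[1]], tolerance = 1e-12)
})

test_that("positivity status follows the two-threshold convention", {
  s <- amyloidStatus(c(1.05, 1.15, 1.25))
  expect_equal(as.character(s), c("negative", "intermediate", "positive"))
  expect_equal(levels(s), c("negative", "intermediate", "positive"))
})

test_that("phase plots render and reject unknown subjects", {
  A <- matrix(c(-0.2, 0, 0, -0.1), 2, 2)
  obs <- linearFieldObservations(A, n = 40L, sigma = 0.02)
  field <- fitVelocityField(obs, restarts = 1L, seed = 2L)
  df <- makeScores(rep(2L, 6), seed = 8L)
  df$suvr <- c(1.0, 1.05, 1.12, 1.18, 1.3, 1.4)[match(df$subject_id,
                                                      unique(df$subject_id))]
  f <- file.path(tempdir(), "dyn.png")
  trajs <- plotDynamics(df, field, shortYears = 2, file = f, h = 0.5)
  expect_length(trajs, 6L)
  if (capabilities("png")) expect_gt(file.info(f)$size, 0)
  expect_error(plotDynamics(df, field, longSubjects = "NOPE", file = f),
               "NOPE")
})
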