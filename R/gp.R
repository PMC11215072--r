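# Gaussian-process regression with anisotropic squared-exponential kernel
# plus white noise; hyperparameters by marginal-likelihood maximization
# (L-BFGS-B on log-parameters, seeded restarts). Written against the needs
# of the velocity-field model: small n, ARD length scales, serializable fit.

.gpPairwiseSq <- function(X) {
  lapply(seq_len(ncol(X)), function(j) outer(X[, j], X[, j], "-")^2)
}

.gpNll <- function(p, D, y, n, jitter = 1e-8) {
  d <- length(D)
  sf2 <- exp(p[1L])
  ls2 <- exp(2 * p[1L + seq_len(d)])
  sn2 <- exp(p[d + 2L])
  M <- matrix(0, n, n)
  for (j in seq_len(d)) M <- M + D[[j]] / ls2[j]
  K <- sf2 * exp(-0.5 * M)
  diag(K) <- diag(K) + sn2 + jitter
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  alpha <- backsolve(R, backsolve(R, y, transpose = TRUE))
  0.5 * sum(y * alpha) + sum(log(diag(R))) + 0.5 * n * log(2 * pi)
}

gpFit <- function(X, y, restarts = 3L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  D <- .gpPairwiseSq(X)
  vy <- max(var(y), 1e-12)
  p0 <- c(log(vy), numeric(d), log(0.1 * vy + 1e-10))
  best <- NULL
  anyConverged <- FALSE
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      start <- if (r == 1L) p0 else p0 + rnorm(length(p0), sd = 0.7)
      fit <- tryCatch(
        optim(start, .gpNll, D = D, y = y, n = n, method = "L-BFGS-B",
              lower = rep(-12, length(p0)), upper = rep(12, length(p0)),
              control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (fit$convergence == 0L) anyConverged <- TRUE
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  if (!anyConverged)
    warning("GP hyperparameter optimization did not converge; ",
            "using best parameters found")
  p <- best$par
  sf2 <- exp(p[1L])
  ls <- exp(p[1L + seq_len(d)])
  sn2 <- exp(p[d + 2L])
  M <- matrix(0, n, n)
  for (j in seq_len(d)) M <- M + D[[j]] / ls[j]^2
  K <- sf2 * exp(-0.5 * M)
  diag(K) <- diag(K) + sn2 + 1e-8
  R <- chol(K)
  alpha <- backsolve(R, backsolve(R, y, transpose = TRUE))
  list(X = X, y = y, sf2 = sf2, ls = ls, sn2 = sn2, R = R, alpha = alpha,
       nll = best$value)
}

gpPredict <- function(gp, Xs) {
  Xs <- if (is.null(dim(Xs))) matrix(Xs, 1L) else as.matrix(Xs)
  m <- nrow(Xs)
  n <- nrow(gp$X)
  M <- matrix(0, m, n)
  for (j in seq_len(ncol(gp$X)))
    M <- M + outer(Xs[, j], gp$X[, j], "-")^2 / gp$ls[j]^2
  kstar <- gp$sf2 * exp(-0.5 * M)
  mean <- as.numeric(kstar %*% gp$alpha)
  a <- backsolve(gp$R, t(kstar), transpose = TRUE)
  var <- pmax(gp$sf2 - colSums(a^2), 0)
  list(mean = mean, var = var)
}
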