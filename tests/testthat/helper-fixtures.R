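# Shared tiny fixtures. Everything is generated in code; heavyweight
# objects are built once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

tinySpec <- function(noiseSigma = 0.02) {
  phantomSpec(gridShape = c(16L, 16L, 16L), noiseSigma = noiseSigma)
}

# small latent table with a planted affine SUVR signal
plantedLatents <- function(n = 120L, L = 8L, sigma = 0, seed = 42L) {
  withSeed(seed, {
    W <- matrix(rnorm(n * L), n, L)
    beta <- c(0.4, -0.25, numeric(L - 2L))
    suvr <- 1.2 + as.numeric(W %*% beta) + rnorm(n, sd = sigma)
    list(W = W, suvr = suvr, beta = beta, intercept = 1.2)
  })
}

# velocity observations drawn from a known linear field V(b) = A b
linearFieldObservations <- function(A, n = 200L, sigma = 0.01, dt = 0.1,
                                    seed = 7L) {
  withSeed(seed, {
    K <- nrow(A)
    rows <- lapply(seq_len(n), function(i) {
      b1 <- runif(K, -1, 1)
      v <- as.numeric(A %*% b1)
      b2 <- b1 + dt * v
      vel <- (b2 - b1) / dt + rnorm(K, sd = sigma)
      state <- (b1 + b2) / 2
      row <- data.frame(subject_id = sprintf("S%03d", i), pair = 1L,
                        t = 0, dt = dt, age = runif(1, 65, 85),
                        apoe4_count = sample(0:2, 1L))
      row[paste0("b", seq_len(K))] <- as.list(state)
      row[paste0("v_b", seq_len(K))] <- as.list(vel)
      row
    })
    obs <- do.call(rbind, rows)
    attr(obs, "scoreCols") <- paste0("b", seq_len(K))
    obs
  })
}

# matrix exponential through the eigendecomposition (independent oracle)
expmEigen <- function(A, t) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values * t), nrow(A)) %*% solve(e$vectors))
}

# tiny untrained GAN + encoder + PCA stack for structural tests
untrainedStack <- function() {
  fixture("untrainedStack", function() {
    gcfg <- tinyGanConfig(volumeShape = c(8L, 8L, 8L), levels = 2L,
                          channels = c(6L, 6L, 4L), zDim = 6L, wDim = 6L,
                          dHidden = 8L, steps = 0L, seed = 3L)
    gan <- initGan(gcfg)
    ecfg <- suppressWarnings(encoderConfig(inputShape = c(8L, 8L, 8L),
                                           filterDepths = c(6L, 6L, 4L),
                                           wDim = 6L, steps = 0L, seed = 3L))
    enc <- initEncoder(ecfg)
    W <- withSeed(9L, matrix(rnorm(40 * 6), 40, 6))
    pca <- fitPca(W, 3L)
    list(gan = gan, enc = enc, pca = pca, gcfg = gcfg, ecfg = ecfg)
  })
}
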