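# Minimal neural-network substrate for volumetric models.
#
# Feature maps are stored as (nvox x channels) matrices with the spatial grid
# dims carried alongside; 3x3x3 same-padded convolutions are evaluated as one
# BLAS matrix product on an im2col patch matrix. Backward passes are written
# by hand; the input gradient of a convolution reuses the forward path with a
# spatially flipped, channel-transposed kernel, so no scatter-add is needed.

.nnCache <- new.env(parent = emptyenv())

.cacheGet <- function(key, build) {
  v <- .nnCache[[key]]
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = .nnCache)
  }
  v
}

# Neighbour indices of every voxel into a 1-voxel zero-padded grid.
neighborIndex <- function(d) {
  .cacheGet(paste0("nb:", paste(d, collapse = "x")), function() {
    d <- as.integer(d)
    dp <- d + 2L
    gx <- rep.int(seq_len(d[1]), d[2] * d[3])
    gy <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
    gz <- rep(seq_len(d[3]), each = d[1] * d[2])
    center <- (gx + 1L) + gy * dp[1] + gz * dp[1] * dp[2]
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
    list(idx = as.vector(outer(center, off, "+")), interior = center,
         npad = prod(dp), nvox = prod(d))
  })
}

im2col <- function(X, d) {
  nb <- neighborIndex(d)
  cin <- ncol(X)
  Xpad <- matrix(0, nb$npad, cin)
  Xpad[nb$interior, ] <- X
  P <- Xpad[nb$idx, , drop = FALSE]
  dim(P) <- c(nb$nvox, 27L * cin)
  P
}

# Kernel weights: (27*cin x cout); rows ordered neighbour-fastest, channel-major.
convForward <- function(X, d, W, b) {
  P <- im2col(X, d)
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, P = P)
}

flipKernel <- function(W, cin) {
  cout <- ncol(W)
  A <- array(W, c(27L, cin, cout))
  A <- A[27:1, , , drop = FALSE]
  A <- aperm(A, c(1L, 3L, 2L))
  matrix(A, 27L * cout, cin)
}

convBackward <- function(dY, d, W, P, cin, paramGrads = TRUE) {
  out <- list(dX = im2col(dY, d) %*% flipKernel(W, cin))
  if (paramGrads) {
    out$dW <- crossprod(P, dY)
    out$db <- colSums(dY)
  }
  out
}

# 2x average-pool ("filtered downsampling"); d must have even axes.
poolIndex <- function(d) {
  .cacheGet(paste0("pool:", paste(d, collapse = "x")), function() {
    d <- as.integer(d)
    do <- d %/% 2L
    ox <- rep.int(seq_len(do[1]), do[2] * do[3])
    oy <- rep.int(rep(seq_len(do[2]), each = do[1]), do[3])
    oz <- rep(seq_len(do[3]), each = do[1] * do[2])
    base <- (2L * ox - 1L) + (2L * oy - 2L) * d[1] + (2L * oz - 2L) * d[1] * d[2]
    offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
    outer(base, off, "+")
  })
}

poolSum <- function(X, d) {
  pidx <- poolIndex(d)
  no <- nrow(pidx)
  cin <- ncol(X)
  A <- X[as.vector(pidx), , drop = FALSE]
  dim(A) <- c(no, 8L, cin)
  Y <- matrix(A[, 1L, ], no, cin)
  for (k in 2:8) Y <- Y + matrix(A[, k, ], no, cin)
  Y
}

avgPoolForward <- function(X, d) poolSum(X, d) / 8

avgPoolBackward <- function(dY, d) {
  pidx <- poolIndex(d)
  no <- nrow(pidx)
  cin <- ncol(dY)
  dX <- matrix(0, prod(d), cin)
  dX[as.vector(pidx), ] <- dY[rep(seq_len(no), 8L), , drop = FALSE] / 8
  dX
}

# Nearest-neighbour 2x upsampling from grid d to 2d.
upIndex <- function(d) {
  .cacheGet(paste0("up:", paste(d, collapse = "x")), function() {
    d <- as.integer(d)
    do <- 2L * d
    ox <- rep.int(seq_len(do[1]), do[2] * do[3])
    oy <- rep.int(rep(seq_len(do[2]), each = do[1]), do[3])
    oz <- rep(seq_len(do[3]), each = do[1] * do[2])
    sx <- (ox + 1L) %/% 2L
    sy <- (oy + 1L) %/% 2L
    sz <- (oz + 1L) %/% 2L
    sx + (sy - 1L) * d[1] + (sz - 1L) * d[1] * d[2]
  })
}

upsampleForward <- function(X, d) X[upIndex(d), , drop = FALSE]

# children of each source voxel form exactly one 2x2x2 pool block of the
# upsampled grid, so the adjoint is a block sum.
upsampleBackward <- function(dY, d) poolSum(dY, 2L * as.integer(d))

lreluForward <- function(X, slope = 0.2) {
  neg <- X < 0
  X[neg] <- slope * X[neg]
  list(Y = X, neg = neg)
}

lreluBackward <- function(dY, neg, slope = 0.2) {
  dY[neg] <- slope * dY[neg]
  dY
}

denseForward <- function(x, W, b) as.vector(x %*% W + b)

# x: input row vector; dy: gradient on the output vector
denseBackward <- function(dy, x, W, paramGrads = TRUE) {
  out <- list(dx = as.vector(W %*% dy))
  if (paramGrads) {
    out$dW <- outer(as.vector(x), dy)
    out$db <- dy
  }
  out
}

heInit <- function(nin, nout, gain = sqrt(2)) {
  matrix(rnorm(nin * nout, sd = gain / sqrt(nin)), nin, nout)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam -------------------------------------------------------------------

adamInit <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamStep <- function(theta, grad, state, lr, beta1 = 0.0, beta2 = 0.99,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
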