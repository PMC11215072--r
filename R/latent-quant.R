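# PCA compression of the latent table and SUVR quantification.

#' @rdname fitPca
#' @export
setClass("PcaModel", representation(
  center = "numeric", components = "matrix", varFractions = "numeric",
  K = "integer"))

setValidity("PcaModel", function(object) {
  msg <- character()
  G <- crossprod(object@components)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "components must be orthonormal to 1e-8")
  vf <- object@varFractions
  if (any(diff(vf) > 1e-12) || sum(vf) > 1 + 1e-8)
    msg <- c(msg, "varFractions must be nonincreasing and sum to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel: K =", object@K, "of L =", length(object@center),
      "| explained variance",
      paste(sprintf("%.3f", object@varFractions), collapse = ", "), "\n")
})

#' Principal component model of a latent table
#'
#' Centred PCA of scan latent vectors. Components are sorted by explained
#' variance and sign-fixed so each component's largest-magnitude coordinate
#' is positive, making fits reproducible across numerical backends.
#'
#' @param latents numeric matrix (scans x L) or data.frame of latent columns.
#' @param K number of components to keep (`K <= min(L, rank)`).
#' @return a `PcaModel` with the cohort mean, `K` orthonormal components and
#'   their explained-variance fractions (relative to total variance).
#' @export
fitPca <- function(latents, K) {
  X <- as.matrix(latents)
  L <- ncol(X)
  if (nrow(X) < K + 1L)
    stop("need at least K+1 = ", K + 1L, " rows, got ", nrow(X))
  if (K > L) stop("K = ", K, " exceeds latent dimension L = ", L)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (K > rank)
    stop("K = ", K, " exceeds the rank of the centred table (", rank, ")")
  V <- pc$rotation[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  vf <- pc$sdev[seq_len(K)]^2 / sum(pc$sdev^2)
  new("PcaModel", center = as.numeric(pc$center), components = V,
      varFractions = vf, K = as.integer(K))
}

#' Project latents onto principal scores / back-project scores to latents
#'
#' `projectScores` maps latent vectors to their K-dimensional principal
#' scores `b_k = v_k . (w - wbar)`; `backProject` returns
#' `wbar + sum_k v_k b_k`, i.e. the point on the PCA hyperplane.
#'
#' @param model a [fitPca()] model.
#' @param w latent vector (length L) or matrix (rows = scans).
#' @param b score vector (length K) or matrix (rows = scans).
#' @return scores (or latents) as a vector for vector input, matrix for
#'   matrix input.
#' @export
projectScores <- function(model, w) {
  vec <- is.null(dim(w))
  W <- if (vec) matrix(w, 1L) else as.matrix(w)
  if (ncol(W) != length(model@center))
    stop("latent dimension ", ncol(W), " does not match model L = ",
         length(model@center))
  B <- sweep(W, 2L, model@center) %*% model@components
  if (vec) as.numeric(B) else B
}

#' @rdname projectScores
#' @export
backProject <- function(model, b) {
  vec <- is.null(dim(b))
  B <- if (vec) matrix(b, 1L) else as.matrix(b)
  if (ncol(B) != model@K)
    stop("score dimension ", ncol(B), " does not match model K = ", model@K)
  W <- sweep(B %*% t(model@components), 2L, model@center, "+")
  if (vec) as.numeric(W) else W
}

#' @rdname fitSuvrRegression
#' @export
setClass("SuvrRegressor", representation(
  weights = "numeric", intercept = "numeric", space = "character"))

setMethod("show", "SuvrRegressor", function(object) {
  cat("SuvrRegressor on", object@space, "features (dim",
      length(object@weights), ")\n")
})

#' Linear SUVR regression on latent features
#'
#' Ordinary least squares with intercept, solved through the SVD
#' pseudoinverse so rank-deficient designs get the minimum-norm solution
#' (with a warning) instead of dropped coefficients.
#'
#' @param features numeric matrix (scans x p): full latents or principal
#'   scores.
#' @param suvr numeric response vector.
#' @param space label recording which feature space was used.
#' @return a `SuvrRegressor`.
#' @export
fitSuvrRegression <- function(features, suvr, space = "latent") {
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(suvr))
  if (nrow(X) < ncol(X) + 1L)
    warning("fewer rows than features + 1; fit is interpolating")
  A <- cbind(1, X)
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  if (sum(keep) < ncol(A))
    warning("rank-deficient design (rank ", sum(keep), " of ", ncol(A),
            "); returning the minimum-norm solution")
  beta <- sv$v[, keep, drop = FALSE] %*%
          ((crossprod(sv$u[, keep, drop = FALSE], suvr)) / sv$d[keep])
  new("SuvrRegressor", weights = as.numeric(beta[-1L]),
      intercept = beta[1L], space = space)
}

#' @rdname fitSuvrRegression
#' @param model a `SuvrRegressor`.
#' @export
predictSuvr <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, 1L) else as.matrix(features)
  if (ncol(X) != length(model@weights))
    stop("feature dimension ", ncol(X), " does not match regressor dim ",
         length(model@weights))
  as.numeric(X %*% model@weights + model@intercept)
}

#' @rdname bootstrapEvaluate
#' @export
setClass("BootstrapReport", representation(
  splits = "data.frame", summary = "data.frame", config = "list"))

setMethod("show", "BootstrapReport", function(object) {
  cat("BootstrapReport over", nrow(object@splits), "splits\n")
  print(object@summary, row.names = FALSE)
  na <- object@config$aurocMissing
  if (!is.null(na) && na > 0)
    cat(na, "split(s) had a single positivity class; AUROC excluded there\n")
})

.aurocOf <- function(labels, scores) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(FALSE, TRUE))))
}

#' Bootstrap evaluation of SUVR prediction
#'
#' Repeated random subject-level train/test splits: all scans of a subject
#' stay on the same side, preventing longitudinal leakage. Each split fits
#' the linear regression on the training scans and reports test RMSE, MAE,
#' and the AUROC of predicted SUVR for classifying observed amyloid
#' positivity (observed SUVR >= `positivityThreshold`). Splits where the
#' test set has a single class contribute no AUROC and are counted.
#'
#' @param features matrix (scans x p) of latent features.
#' @param suvr observed SUVR per scan.
#' @param subjects subject identifier per scan (controls the split unit);
#'   defaults to one subject per scan.
#' @param nSplits number of random splits (>= 2).
#' @param testFraction fraction of subjects held out (0 < f < 1).
#' @param positivityThreshold SUVR cut-point for the positivity label.
#' @param seed integer seed; the full report is deterministic given it.
#' @return a `BootstrapReport` with per-split metrics and mean / 95%
#'   percentile-CI summaries.
#' @export
bootstrapEvaluate <- function(features, suvr, subjects = NULL,
                              nSplits = 1000L, testFraction = 0.35,
                              positivityThreshold = 1.1, seed = 1L) {
  stopifnot(nSplits >= 2L, testFraction > 0, testFraction < 1)
  X <- as.matrix(features)
  n <- nrow(X)
  subjects <- subjects %||% as.character(seq_len(n))
  stopifnot(length(subjects) == n, length(suvr) == n)
  ids <- unique(subjects)
  nTest <- max(1L, round(testFraction * length(ids)))
  if (nTest >= length(ids)) stop("test fraction leaves no training subjects")
  withSeed(seed, {
    rows <- vector("list", nSplits)
    for (s in seq_len(nSplits)) {
      testIds <- sample(ids, nTest)
      te <- subjects %in% testIds
      fit <- suppressWarnings(fitSuvrRegression(X[!te, , drop = FALSE],
                                                suvr[!te]))
      pred <- predictSuvr(fit, X[te, , drop = FALSE])
      err <- pred - suvr[te]
      rows[[s]] <- data.frame(
        split = s, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
        auroc = .aurocOf(suvr[te] >= positivityThreshold, pred))
    }
    splits <- do.call(rbind, rows)
    summarize <- function(x) {
      x <- x[!is.na(x)]
      c(mean = mean(x), lower = unname(quantile(x, 0.025)),
        upper = unname(quantile(x, 0.975)))
    }
    sm <- t(vapply(splits[c("rmse", "mae", "auroc")], summarize, numeric(3)))
    summary <- data.frame(metric = rownames(sm), sm, row.names = NULL)
    new("BootstrapReport", splits = splits, summary = summary,
        config = list(nSplits = nSplits, testFraction = testFraction,
                      positivityThreshold = positivityThreshold, seed = seed,
                      aurocMissing = sum(is.na(splits$auroc))))
  })
}

#' Metric summary of a bootstrap report
#' @param report a `BootstrapReport`.
#' @param metric one of "rmse", "mae", "auroc".
#' @return named numeric: mean, lower, upper.
#' @export
reportMetric <- function(report, metric = c("rmse", "mae", "auroc")) {
  metric <- match.arg(metric)
  row <- report@summary[report@summary$metric == metric, ]
  c(mean = row$mean, lower = row$lower, upper = row$upper)
}

#' SUVR prediction error versus number of principal components
#'
#' Fits one PCA on the full latent table, then bootstrap-evaluates the SUVR
#' regression on the first K principal scores for each requested K,
#' producing the elbow curve used to choose the progression subspace.
#'
#' @inheritParams bootstrapEvaluate
#' @param latents matrix (scans x L) of latent vectors.
#' @param Ks integer vector of component counts (all `<= L`).
#' @param nSplits splits per K (default 100).
#' @param plotFile optional path for a PNG of the curve.
#' @return data.frame: K, rmse_mean, rmse_lower, rmse_upper.
#' @export
elbowCurve <- function(latents, suvr, subjects = NULL, Ks = 1:10,
                       nSplits = 100L, testFraction = 0.35,
                       positivityThreshold = 1.1, seed = 1L,
                       plotFile = NULL) {
  X <- as.matrix(latents)
  stopifnot(all(Ks <= ncol(X)))
  pca <- fitPca(X, max(Ks))
  scores <- projectScores(pca, X)
  rows <- lapply(Ks, function(K) {
    rep_ <- bootstrapEvaluate(scores[, seq_len(K), drop = FALSE], suvr,
                              subjects, nSplits = nSplits,
                              testFraction = testFraction,
                              positivityThreshold = positivityThreshold,
                              seed = stageSeed(seed, paste0("elbow-K", K)))
    m <- reportMetric(rep_, "rmse")
    data.frame(K = K, rmse_mean = m["mean"], rmse_lower = m["lower"],
               rmse_upper = m["upper"], row.names = NULL)
  })
  curve <- do.call(rbind, rows)
  if (!is.null(plotFile) && capabilities("png")) {
    grDevices::png(plotFile, width = 600, height = 450)
    on.exit(grDevices::dev.off())
    plot(curve$K, curve$rmse_mean, type = "b", pch = 19,
         xlab = "number of principal components",
         ylab = "bootstrap SUVR RMSE",
         ylim = range(curve$rmse_lower, curve$rmse_upper))
    graphics::arrows(curve$K, curve$rmse_lower, curve$K, curve$rmse_upper,
                     angle = 90, code = 3, length = 0.04)
  }
  curve
}
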