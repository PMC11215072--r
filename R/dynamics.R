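# Non-parametric ODE progression model in principal-score space:
# finite-difference velocity observations, per-component GP regression of
# the velocity field V(b, c), forward-Euler trajectory integration, and
# synthetic image-trajectory generation through the generator.

.scoreCols <- function(df) {
  reserved <- c("subject_id", "scan_time_years", "age", "apoe4_count",
                "suvr", "diagnosis", "nifti_path", "true_load", "pair",
                "t", "dt")
  nm <- setdiff(names(df), reserved)
  nm[vapply(df[nm], is.numeric, logical(1))]
}

#' Finite-difference velocity observations from longitudinal scores
#'
#' One observation per consecutive same-subject scan pair: the velocity is
#' `(b2 - b1) / (t2 - t1)` per year; by default the observation is placed at
#' the pair midpoint in both state and age (central-difference reasoning),
#' optionally at the first scan of the pair. Subjects with a single scan
#' contribute nothing; pairs closer than `minDt` years are skipped with a
#' message.
#'
#' @param scores data.frame with columns `subject_id`, `scan_time_years`,
#'   the principal-score columns, and (or merged from `covariates`) `age`
#'   and `apoe4_count`.
#' @param covariates optional data.frame keyed by `subject_id` and
#'   `scan_time_years` carrying `age` and `apoe4_count` per scan.
#' @param evaluation where to place each observation: "midpoint" or "start".
#' @param minDt minimum scan interval in years; shorter pairs are skipped.
#' @return data.frame with columns `subject_id`, `pair`, `t`, `dt`, `age`,
#'   `apoe4_count`, the evaluation-state columns and velocity columns
#'   (`v_<score>`); attribute `skipped` counts short-interval pairs.
#' @export
finiteDifferenceVelocities <- function(scores, covariates = NULL,
                                       evaluation = c("midpoint", "start"),
                                       minDt = 0.25) {
  evaluation <- match.arg(evaluation)
  stopifnot(all(c("subject_id", "scan_time_years") %in% names(scores)))
  if (!is.null(covariates)) {
    keep <- c("subject_id", "scan_time_years",
              intersect(c("age", "apoe4_count"), names(covariates)))
    scores <- merge(scores, covariates[keep],
                    by = c("subject_id", "scan_time_years"), sort = FALSE)
  }
  if (!all(c("age", "apoe4_count") %in% names(scores)))
    stop("covariates 'age' and 'apoe4_count' are required")
  cols <- .scoreCols(scores)
  if (length(cols) == 0L) stop("no score columns found")
  scores <- scores[order(scores$subject_id, scores$scan_time_years), ]
  dup <- stats::aggregate(scan_time_years ~ subject_id, scores,
                          function(t) anyDuplicated(t) > 0)
  if (any(dup$scan_time_years))
    stop("duplicate scan times within subject(s): ",
         paste(dup$subject_id[dup$scan_time_years], collapse = ", "))
  out <- list()
  skipped <- 0L
  for (sid in unique(scores$subject_id)) {
    sub <- scores[scores$subject_id == sid, ]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      dt <- sub$scan_time_years[i + 1L] - sub$scan_time_years[i]
      if (dt < minDt) {
        skipped <- skipped + 1L
        next
      }
      b1 <- as.numeric(sub[i, cols])
      b2 <- as.numeric(sub[i + 1L, cols])
      vel <- (b2 - b1) / dt
      if (evaluation == "midpoint") {
        state <- (b1 + b2) / 2
        age <- (sub$age[i] + sub$age[i + 1L]) / 2
        tMid <- (sub$scan_time_years[i] + sub$scan_time_years[i + 1L]) / 2
      } else {
        state <- b1
        age <- sub$age[i]
        tMid <- sub$scan_time_years[i]
      }
      row <- data.frame(subject_id = sid, pair = i, t = tMid, dt = dt,
                        age = age, apoe4_count = sub$apoe4_count[i],
                        stringsAsFactors = FALSE)
      row[cols] <- as.list(state)
      row[paste0("v_", cols)] <- as.list(vel)
      out[[length(out) + 1L]] <- row
    }
  }
  if (skipped > 0L)
    message(skipped, " scan pair(s) below the ", minDt,
            "-year interval floor were skipped")
  res <- if (length(out)) do.call(rbind, out) else
    stop("no usable consecutive scan pairs (need >= 2 scans for a subject)")
  attr(res, "skipped") <- skipped
  attr(res, "scoreCols") <- cols
  res
}

#' @rdname fitVelocityField
#' @export
setClass("VelocityFieldModel", representation(
  gps = "list", center = "numeric", scale = "numeric",
  targetMeans = "numeric", scoreCols = "character",
  covariateCols = "character", K = "integer"))

setMethod("show", "VelocityFieldModel", function(object) {
  cat("VelocityFieldModel:", object@K, "GP components over inputs (",
      paste(c(object@scoreCols, object@covariateCols), collapse = ", "),
      ");", nrow(object@gps[[1L]]$X), "observations\n")
})

#' Gaussian-process velocity field over principal scores and covariates
#'
#' Fits one independent GP per score component to the finite-difference
#' velocity observations, with an anisotropic squared-exponential kernel
#' plus white noise. Inputs (state and covariates) are z-scored internally;
#' targets are de-meaned per component. Hyperparameters are set by marginal
#' likelihood maximization with seeded restarts.
#'
#' @param velocities output of [finiteDifferenceVelocities()].
#' @param covariateCols covariate columns to include as GP inputs.
#' @param restarts number of seeded optimizer restarts per component.
#' @param seed integer seed.
#' @return a `VelocityFieldModel`.
#' @export
fitVelocityField <- function(velocities, covariateCols = c("age", "apoe4_count"),
                             restarts = 3L, seed = 1L) {
  cols <- attr(velocities, "scoreCols") %||%
    sub("^v_", "", grep("^v_", names(velocities), value = TRUE))
  vcols <- paste0("v_", cols)
  stopifnot(all(cols %in% names(velocities)), all(vcols %in% names(velocities)))
  if (nrow(velocities) < 5L)
    stop("need at least 5 velocity observations, got ", nrow(velocities))
  Xraw <- as.matrix(velocities[c(cols, covariateCols)])
  if (all(apply(Xraw[, cols, drop = FALSE], 2L, function(x) sd(x) == 0)))
    stop("degenerate observations: all evaluation states are identical")
  center <- colMeans(Xraw)
  scale <- apply(Xraw, 2L, sd)
  scale[scale < 1e-12] <- 1
  X <- sweep(sweep(Xraw, 2L, center), 2L, scale, "/")
  targetMeans <- colMeans(as.matrix(velocities[vcols]))
  gps <- lapply(seq_along(cols), function(k) {
    y <- velocities[[vcols[k]]] - targetMeans[k]
    gpFit(X, y, restarts = restarts, seed = stageSeed(seed, paste0("gp-", k)))
  })
  new("VelocityFieldModel", gps = gps, center = center, scale = scale,
      targetMeans = as.numeric(targetMeans), scoreCols = cols,
      covariateCols = covariateCols, K = length(cols))
}

#' Predict the latent velocity at given states and covariates
#'
#' @param model a `VelocityFieldModel`.
#' @param b score vector (length K) or matrix (rows = evaluation points).
#' @param covariates named numeric vector (e.g. `c(age = 75, apoe4_count
#'   = 1)`) or matrix/data.frame with one row per evaluation point.
#' @return list with `mean` and `var` (per-component posterior mean and
#'   variance), each a K-vector or (points x K) matrix.
#' @export
predictVelocity <- function(model, b, covariates) {
  vec <- is.null(dim(b))
  B <- if (vec) matrix(b, 1L) else as.matrix(b)
  if (ncol(B) != model@K)
    stop("state dimension ", ncol(B), " does not match model K = ", model@K)
  C <- if (is.null(dim(covariates)))
    matrix(rep(as.numeric(covariates[model@covariateCols]), each = nrow(B)),
           nrow(B), dimnames = list(NULL, model@covariateCols))
  else as.matrix(as.data.frame(covariates)[model@covariateCols])
  Xraw <- cbind(B, C)
  X <- sweep(sweep(Xraw, 2L, model@center), 2L, model@scale, "/")
  preds <- lapply(model@gps, gpPredict, Xs = X)
  mean <- vapply(seq_len(model@K),
                 function(k) preds[[k]]$mean + model@targetMeans[k],
                 numeric(nrow(X)))
  varm <- vapply(seq_len(model@K), function(k) preds[[k]]$var,
                 numeric(nrow(X)))
  mean <- matrix(mean, nrow(X), model@K)
  varm <- matrix(varm, nrow(X), model@K)
  if (vec) list(mean = as.numeric(mean), var = as.numeric(varm))
  else list(mean = mean, var = varm)
}

#' @rdname integrateTrajectory
#' @export
setClass("Trajectory", representation(
  times = "numeric", states = "matrix", covariates = "numeric",
  h = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) != nrow(object@states))
    msg <- c(msg, "times and states disagree in length")
  if (object@times[1L] != 0 || any(diff(object@times) <= 0))
    msg <- c(msg, "times must strictly increase from 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@states) - 1L, "Euler steps (h =", object@h,
      "y) over", max(object@times), "years in", ncol(object@states),
      "dimensions\n")
})

#' @rdname integrateTrajectory
#' @export
trajectoryTimes <- function(x) x@times
#' @rdname integrateTrajectory
#' @export
trajectoryStates <- function(x) x@states

#' Forward-Euler integration of the latent velocity field
#'
#' `b_{n+1} = b_n + h V(b_n, c(t_n))`; the age covariate advances with
#' integration time (`age(t) = age(0) + t`) so long-horizon forecasts age
#' the subject. The full path is recorded at every step, the initial state
#' exactly.
#'
#' @param b0 initial score vector.
#' @param covariates named numeric vector with entries matching the field's
#'   covariate columns (e.g. age, apoe4_count).
#' @param duration years to integrate (>= 0).
#' @param h Euler step in years (> 0).
#' @param model a `VelocityFieldModel`, or a function `f(b, covariates)`
#'   returning the velocity vector (analytic fields for testing).
#' @param ageAdvances logical; set `FALSE` to freeze the age covariate.
#' @return a `Trajectory`.
#' @export
integrateTrajectory <- function(b0, covariates, duration, h = 0.01, model,
                                ageAdvances = TRUE) {
  stopifnot(h > 0, duration >= 0)
  b0 <- as.numeric(b0)
  times <- seq(0, duration, by = h)
  if (max(times) < duration) times <- c(times, duration)
  states <- matrix(NA_real_, length(times), length(b0))
  states[1L, ] <- b0
  b <- b0
  isField <- is(model, "VelocityFieldModel")
  for (i in seq_len(length(times) - 1L)) {
    cv <- covariates
    if (ageAdvances && "age" %in% names(cv)) cv["age"] <- cv["age"] + times[i]
    v <- if (isField) predictVelocity(model, b, cv)$mean
         else as.numeric(model(b, cv))
    b <- b + (times[i + 1L] - times[i]) * v
    if (any(!is.finite(b)))
      stop("non-finite state at step ", i, "; last finite state: ",
           paste(signif(states[i, ], 4), collapse = ", "))
    states[i + 1L, ] <- b
  }
  new("Trajectory", times = times, states = states,
      covariates = if (is.numeric(covariates)) covariates else numeric(),
      h = h)
}

.stateAt <- function(traj, t) {
  tm <- traj@times
  j <- findInterval(t, tm)
  if (j >= length(tm)) return(traj@states[length(tm), ])
  if (abs(tm[j] - t) < 1e-9) return(traj@states[j, ])
  f <- (t - tm[j]) / (tm[j + 1L] - tm[j])
  (1 - f) * traj@states[j, ] + f * traj@states[j + 1L, ]
}

#' Generate a synthetic PET image trajectory from a baseline volume
#'
#' Encodes the baseline into latent space, projects onto the PCA subspace,
#' integrates the velocity field to each requested time, back-projects onto
#' the latent hyperplane and renders through the generator. At `t = 0` the
#' output is exactly the reconstruction
#' `G(backProject(project(E(baseline))))`.
#'
#' @param baseline 3D array, the baseline volume (already normalized the way
#'   the encoder's training volumes were).
#' @param covariates named numeric vector (age, apoe4_count).
#' @param times sorted nonnegative times in years, starting at 0.
#' @param encoder an `EncoderModel`.
#' @param gan a `GanModel`.
#' @param pca a `PcaModel` fitted on the cohort latents.
#' @param field a `VelocityFieldModel` (or analytic function, see
#'   [integrateTrajectory()]).
#' @param h Euler step in years.
#' @return list with `times`, `scores` (states at the requested times),
#'   `volumes` (rendered arrays) and `differences` (each volume minus the
#'   `t = 0` rendering).
#' @export
generateImageTrajectory <- function(baseline, covariates, times, encoder,
                                    gan, pca, field, h = 0.1) {
  stopifnot(length(times) >= 1L, times[1L] == 0, !is.unsorted(times))
  w0 <- encodeVolume(encoder, baseline)
  b0 <- projectScores(pca, w0)
  traj <- if (max(times) > 0)
    integrateTrajectory(b0, covariates, max(times), h = h, model = field)
  else NULL
  scores <- t(vapply(times, function(t) {
    if (t == 0) b0 else .stateAt(traj, t)
  }, numeric(length(b0))))
  volumes <- lapply(seq_along(times), function(i)
    synthesize(gan, backProject(pca, scores[i, ])))
  differences <- lapply(volumes, function(v) v - volumes[[1L]])
  list(times = times, scores = scores, volumes = volumes,
       differences = differences)
}

#' Amyloid positivity status from SUVR
#'
#' Standard two-threshold convention: negative below the lower threshold,
#' positive above the upper, intermediate in between.
#'
#' @param suvr numeric SUVR values.
#' @param thresholds length-2 numeric `c(lower, upper)`, default 1.1 / 1.2.
#' @return factor with levels negative, intermediate, positive.
#' @export
amyloidStatus <- function(suvr, thresholds = c(1.1, 1.2)) {
  factor(ifelse(suvr < thresholds[1L], "negative",
         ifelse(suvr > thresholds[2L], "positive", "intermediate")),
         levels = c("negative", "intermediate", "positive"))
}

#' Phase plot of latent amyloid dynamics
#'
#' Scatter of baseline principal scores on a chosen component pair, colored
#' by amyloid positivity (blue negative, green intermediate, red positive),
#' with thin short-horizon trajectories from every baseline and thick
#' long-horizon trajectories for selected subjects.
#'
#' @param scores data.frame with `subject_id`, `scan_time_years`, `age`,
#'   `apoe4_count`, `suvr` and the score columns.
#' @param field a `VelocityFieldModel`.
#' @param pcPair indices of the two components to display.
#' @param shortYears horizon of the thin trajectories (years).
#' @param longSubjects subject ids drawn with thick `longYears` trajectories.
#' @param longYears horizon of the thick trajectories.
#' @param thresholds SUVR positivity thresholds, see [amyloidStatus()].
#' @param file output PNG path.
#' @param h Euler step for the displayed trajectories.
#' @return invisibly, the list of short-horizon trajectories.
#' @export
plotDynamics <- function(scores, field, pcPair = c(1L, 2L), shortYears = 5,
                         longSubjects = character(), longYears = 15,
                         thresholds = c(1.1, 1.2), file = "dynamics.png",
                         h = 0.1) {
  cols <- field@scoreCols
  stopifnot(all(pcPair <= length(cols)))
  base <- scores[order(scores$subject_id, scores$scan_time_years), ]
  base <- base[!duplicated(base$subject_id), ]
  unknown <- setdiff(longSubjects, base$subject_id)
  if (length(unknown))
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "))
  status <- amyloidStatus(base$suvr, thresholds)
  palette <- c(negative = "#2166ac", intermediate = "#1b7837",
               positive = "#b2182b")
  trajs <- lapply(seq_len(nrow(base)), function(i) {
    integrateTrajectory(as.numeric(base[i, cols]),
                        c(age = base$age[i],
                          apoe4_count = base$apoe4_count[i]),
                        shortYears, h = h, model = field)
  })
  canPlot <- capabilities("png")
  if (canPlot) {
    grDevices::png(file, width = 700, height = 600)
    on.exit(grDevices::dev.off())
    xy <- as.matrix(base[, cols[pcPair]])
    lim <- apply(do.call(rbind, lapply(trajs, function(tr)
      tr@states[, pcPair])), 2L, range)
    plot(xy, col = palette[as.character(status)], pch = 19,
         xlab = paste("PC", pcPair[1L]), ylab = paste("PC", pcPair[2L]),
         xlim = lim[, 1L], ylim = lim[, 2L],
         main = sprintf("%g-year latent amyloid dynamics", shortYears))
    for (i in seq_along(trajs)) {
      st <- trajs[[i]]@states
      graphics::lines(st[, pcPair[1L]], st[, pcPair[2L]],
                      col = grDevices::adjustcolor(
                        palette[as.character(status[i])], alpha.f = 0.35))
    }
    for (sid in longSubjects) {
      i <- match(sid, base$subject_id)
      tr <- integrateTrajectory(as.numeric(base[i, cols]),
                                c(age = base$age[i],
                                  apoe4_count = base$apoe4_count[i]),
                                longYears, h = h, model = field)
      graphics::lines(tr@states[, pcPair[1L]], tr@states[, pcPair[2L]],
                      lwd = 3, col = palette[as.character(status[i])])
    }
    graphics::legend("topright", legend = levels(status), col = palette,
                     pch = 19, bty = "n")
  }
  invisible(trajs)
}
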