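# End-to-end pipeline orchestration: composable stages with one config, a
# global seed fanned out per stage, and JSON manifests recording inputs,
# config hash, seed and output checksums.

.tinyProfile <- function() list(
  profile = "tiny",
  seed = 1L,
  paths = list(output_dir = "amyloid-dyn-output"),
  phantom = list(
    n_subjects = 64L, grid_shape = c(16L, 16L, 16L), voxel_size_mm = 1.5,
    noise_sigma = 0.02, anatomy_jitter = 0.03,
    base_rate = 0.25, a_max = 1.0, apoe_multiplier = 1.5,
    suvr_offset = 1.0, suvr_slope = 1.0,
    visit_count_probs = c(0.25, 0.35, 0.25, 0.15)),
  gan = list(
    z_dim = 16L, w_dim = 16L, mapping_depth = 8L, levels = 2L,
    channels = c(12L, 12L, 8L), d_hidden = 32L, steps = 400L,
    batch_size = 4L, lr_g = 5e-4, lr_d = 1e-3, r1_weight = 1.0),
  encoder = list(
    filter_depths = c(16L, 32L, 32L, 32L, 16L), steps = 800L,
    batch_size = 4L, lr = 5e-4, synthetic_fraction = 0.5,
    latent_weight = 0.3),
  pca = list(K = 5L),
  regression = list(n_splits = 200L, test_fraction = 0.35,
                    positivity_threshold = 1.1),
  elbow = list(Ks = 1:8, n_splits = 50L),
  dynamics = list(restarts = 3L, min_dt = 0.25, evaluation = "midpoint"),
  forecast = list(horizon_years = 4, h = 0.1),
  render = list(times = c(0, 4), h = 0.1, window = c(-0.4, 0.4)),
  plot = list(pc_pair = c(1L, 2L), short_years = 5, long_years = 15))

.paperScaleProfile <- function() {
  # GPU-scale profile: config-complete, excluded from the test suite.
  modifyList(.tinyProfile(), list(
    profile = "paper-scale",
    phantom = list(n_subjects = 1259L, grid_shape = c(160L, 160L, 96L),
                   voxel_size_mm = 1.5),
    gan = list(z_dim = 96L, w_dim = 96L, mapping_depth = 8L, levels = 5L,
               channels = c(64L, 64L, 48L, 32L, 24L, 16L), d_hidden = 64L,
               steps = 100000L, batch_size = 4L),
    encoder = list(steps = 20000L, synthetic_fraction = 0,
                   latent_weight = 0),
    regression = list(n_splits = 1000L),
    elbow = list(Ks = c(1:10, 15L, 20L, 48L, 96L), n_splits = 100L)))
}

#' Pipeline configuration
#'
#' Builds the full pipeline configuration from a profile plus overrides.
#' `x` may be a YAML file path, a list of overrides, or `NULL` for profile
#' defaults. The "tiny" profile is CPU-scale and drives the test pipeline;
#' "paper-scale" mirrors the full 160 x 160 x 96 / 96-dim setup and is
#' GPU-scale.
#'
#' @param x YAML path, list of overrides, or NULL.
#' @param profile "tiny" or "paper-scale"; overridden by a `profile` field
#'   in `x`.
#' @return a nested configuration list.
#' @export
pipelineConfig <- function(x = NULL, profile = "tiny") {
  overrides <- if (is.character(x)) yaml::read_yaml(x) else (x %||% list())
  profile <- overrides$profile %||% profile
  base <- switch(profile, tiny = .tinyProfile(),
                 "paper-scale" = .paperScaleProfile(),
                 stop("unknown profile: ", profile))
  cfg <- modifyList(base, overrides)
  if (cfg$gan$w_dim != cfg$gan$z_dim && is.null(overrides$gan$z_dim)) {
    cfg$gan$z_dim <- cfg$gan$w_dim
  }
  cfg
}

.specFromConfig <- function(config) {
  ph <- config$phantom
  phantomSpec(gridShape = ph$grid_shape, voxelSizeMm = ph$voxel_size_mm,
              noiseSigma = ph$noise_sigma, seed = config$seed)
}

.dynamicsFromConfig <- function(config) {
  ph <- config$phantom
  groundTruthDynamics(baseRate = ph$base_rate, aMax = ph$a_max,
                      apoeMultiplier = ph$apoe_multiplier,
                      suvrOffset = ph$suvr_offset, suvrSlope = ph$suvr_slope)
}

.ganConfigFrom <- function(config, seed) {
  g <- config$gan
  ganConfig(volumeShape = config$phantom$grid_shape, zDim = g$z_dim,
            wDim = g$w_dim, mappingDepth = g$mapping_depth,
            levels = g$levels, channels = g$channels, dHidden = g$d_hidden,
            lrG = g$lr_g, lrD = g$lr_d, r1Weight = g$r1_weight,
            steps = g$steps, batchSize = g$batch_size, seed = seed)
}

.encoderConfigFrom <- function(config, seed) {
  e <- config$encoder
  suppressWarnings(encoderConfig(
    inputShape = config$phantom$grid_shape, filterDepths = e$filter_depths,
    wDim = config$gan$w_dim, lr = e$lr, steps = e$steps,
    batchSize = e$batch_size,
    syntheticFraction = e$synthetic_fraction %||% 0,
    latentWeight = e$latent_weight %||% 0, seed = seed))
}

.stagePath <- function(config, stage, ...) {
  file.path(config$paths$output_dir, stage, ...)
}

.requireArtifact <- function(path, producedBy) {
  if (!file.exists(path))
    stop("missing artifact '", path, "'; run stage '", producedBy,
         "' first", call. = FALSE)
  path
}

.writeManifest <- function(config, stage, inputs, outputs, seed) {
  manifest <- list(
    stage = stage,
    inputs = as.list(inputs),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))),
    configHash = objectHash(config),
    seed = seed,
    package = as.character(utils::packageVersion("AmyloidDyn")))
  path <- .stagePath(config, stage, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}

.loadCohortVolumes <- function(config, normalize = TRUE) {
  dir <- .stagePath(config, "simulate-cohort")
  cohort <- read.csv(.requireArtifact(file.path(dir, "cohort.csv"),
                                      "simulate-cohort"),
                     stringsAsFactors = FALSE)
  spec <- .specFromConfig(config)
  masks <- phantomMasks(spec)
  volumes <- lapply(cohort$nifti_path, function(p) {
    v <- array(as.numeric(RNifti::readNifti(file.path(dir, p))),
               dim = spec@gridShape)
    if (normalize) normalizeVolume(v, masks$reference) else v
  })
  list(cohort = cohort, volumes = volumes, spec = spec, masks = masks)
}

.readLatents <- function(config) {
  path <- .requireArtifact(.stagePath(config, "embed", "latents.csv"), "embed")
  df <- read.csv(path, stringsAsFactors = FALSE)
  wCols <- grep("^w_", names(df), value = TRUE)
  list(table = df, W = as.matrix(df[wCols]), wCols = wCols)
}

.readPca <- function(config) {
  path <- .requireArtifact(.stagePath(config, "fit-pca", "pca.json"),
                          "fit-pca")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PcaModel", center = j$center,
      components = matrix(j$components, ncol = j$K),
      varFractions = j$varFractions, K = as.integer(j$K))
}

.scoresTable <- function(config) {
  lat <- .readLatents(config)
  pca <- .readPca(config)
  B <- projectScores(pca, lat$W)
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  cbind(lat$table[c("subject_id", "scan_time_years", "age", "apoe4_count",
                    "suvr")], as.data.frame(B))
}

#' Run one pipeline stage
#'
#' Stages: simulate-cohort, train-gan, train-encoder, embed, fit-pca,
#' fit-suvr, evaluate-suvr, elbow, fit-dynamics, forecast,
#' render-trajectory, plot-dynamics. Each stage reads only upstream
#' artifacts, writes its outputs under `<output_dir>/<stage>/` and records a
#' JSON manifest (inputs, config hash, seed, output checksums). Missing
#' upstream artifacts raise an error naming the stage to run first.
#'
#' @param stage stage name.
#' @param config a [pipelineConfig()].
#' @return the manifest, invisibly.
#' @export
runStage <- function(stage, config = pipelineConfig()) {
  stages <- c("simulate-cohort", "train-gan", "train-encoder", "embed",
              "fit-pca", "fit-suvr", "evaluate-suvr", "elbow",
              "fit-dynamics", "forecast", "render-trajectory",
              "plot-dynamics")
  stage <- match.arg(stage, stages)
  seed <- stageSeed(config$seed, stage)
  out <- .stagePath(config, stage)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- switch(
    stage,
    "simulate-cohort" = .stageSimulateCohort(config, out, seed),
    "train-gan" = .stageTrainGan(config, out, seed),
    "train-encoder" = .stageTrainEncoder(config, out, seed),
    "embed" = .stageEmbed(config, out, seed),
    "fit-pca" = .stageFitPca(config, out, seed),
    "fit-suvr" = .stageFitSuvr(config, out, seed),
    "evaluate-suvr" = .stageEvaluateSuvr(config, out, seed),
    "elbow" = .stageElbow(config, out, seed),
    "fit-dynamics" = .stageFitDynamics(config, out, seed),
    "forecast" = .stageForecast(config, out, seed),
    "render-trajectory" = .stageRender(config, out, seed),
    "plot-dynamics" = .stagePlot(config, out, seed))
  invisible(manifest)
}

#' @rdname runStage
#' @param stages stage names to run, in order.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate-cohort", "train-gan",
                                   "train-encoder", "embed", "fit-pca",
                                   "fit-suvr", "evaluate-suvr", "elbow",
                                   "fit-dynamics", "forecast",
                                   "render-trajectory", "plot-dynamics")) {
  manifests <- lapply(stages, runStage, config = config)
  names(manifests) <- stages
  invisible(manifests)
}

.stageSimulateCohort <- function(config, out, seed) {
  ph <- config$phantom
  simulateCohort(ph$n_subjects, .dynamicsFromConfig(config),
                 .specFromConfig(config), outDir = out,
                 visitCountProbs = ph$visit_count_probs,
                 anatomyJitter = ph$anatomy_jitter, seed = seed)
  .writeManifest(config, "simulate-cohort", character(),
                 file.path(out, c("cohort.csv", "truth.json")), seed)
}

.stageTrainGan <- function(config, out, seed) {
  dat <- .loadCohortVolumes(config)
  cfg <- .ganConfigFrom(config, seed)
  res <- trainGan(dat$volumes, cfg)
  ck <- file.path(out, "gan.rds")
  saveCheckpoint(res$model, ck)
  write.csv(res$log, file.path(out, "gan_loss.csv"), row.names = FALSE)
  .writeManifest(config, "train-gan",
                 .stagePath(config, "simulate-cohort", "cohort.csv"),
                 c(ck, file.path(out, "gan_loss.csv")), seed)
}

.stageTrainEncoder <- function(config, out, seed) {
  ganPath <- .requireArtifact(.stagePath(config, "train-gan", "gan.rds"),
                              "train-gan")
  gan <- loadCheckpoint(ganPath)
  dat <- .loadCohortVolumes(config)
  cfg <- .encoderConfigFrom(config, seed)
  res <- trainEncoder(dat$volumes, gan, cfg)
  ck <- file.path(out, "encoder.rds")
  saveCheckpoint(res$model, ck)
  write.csv(res$log, file.path(out, "encoder_loss.csv"), row.names = FALSE)
  .writeManifest(config, "train-encoder", ganPath,
                 c(ck, file.path(out, "encoder_loss.csv")), seed)
}

.stageEmbed <- function(config, out, seed) {
  encPath <- .requireArtifact(
    .stagePath(config, "train-encoder", "encoder.rds"), "train-encoder")
  enc <- loadCheckpoint(encPath)
  dat <- .loadCohortVolumes(config)
  W <- t(vapply(dat$volumes, function(v) encodeVolume(enc, v),
                numeric(modelConfig(enc)@wDim)))
  colnames(W) <- paste0("w_", seq_len(ncol(W)))
  tab <- cbind(dat$cohort[c("subject_id", "scan_time_years", "age",
                            "apoe4_count", "suvr")], as.data.frame(W))
  path <- file.path(out, "latents.csv")
  write.csv(tab, path, row.names = FALSE)
  .writeManifest(config, "embed", encPath, path, seed)
}

.stageFitPca <- function(config, out, seed) {
  lat <- .readLatents(config)
  pca <- fitPca(lat$W, config$pca$K)
  path <- file.path(out, "pca.json")
  jsonlite::write_json(
    list(center = pca@center, components = as.numeric(pca@components),
         varFractions = pca@varFractions, K = pca@K),
    path, auto_unbox = TRUE, digits = NA)
  .writeManifest(config, "fit-pca",
                 .stagePath(config, "embed", "latents.csv"), path, seed)
}

.stageFitSuvr <- function(config, out, seed) {
  lat <- .readLatents(config)
  fit <- fitSuvrRegression(lat$W, lat$table$suvr, space = "latent")
  path <- file.path(out, "suvr_model.json")
  jsonlite::write_json(
    list(weights = fit@weights, intercept = fit@intercept, space = fit@space),
    path, auto_unbox = TRUE, digits = NA)
  .writeManifest(config, "fit-suvr",
                 .stagePath(config, "embed", "latents.csv"), path, seed)
}

.stageEvaluateSuvr <- function(config, out, seed) {
  lat <- .readLatents(config)
  rg <- config$regression
  report <- bootstrapEvaluate(lat$W, lat$table$suvr, lat$table$subject_id,
                              nSplits = rg$n_splits,
                              testFraction = rg$test_fraction,
                              positivityThreshold = rg$positivity_threshold,
                              seed = seed)
  jpath <- file.path(out, "bootstrap_report.json")
  jsonlite::write_json(
    list(summary = report@summary, config = report@config),
    jpath, auto_unbox = TRUE, digits = NA)
  tpath <- file.path(out, "bootstrap_report.txt")
  txt <- utils::capture.output(show(report))
  writeLines(txt, tpath)
  .writeManifest(config, "evaluate-suvr",
                 .stagePath(config, "embed", "latents.csv"),
                 c(jpath, tpath), seed)
}

.stageElbow <- function(config, out, seed) {
  lat <- .readLatents(config)
  eb <- config$elbow
  curve <- elbowCurve(lat$W, lat$table$suvr, lat$table$subject_id,
                      Ks = eb$Ks, nSplits = eb$n_splits,
                      testFraction = config$regression$test_fraction,
                      positivityThreshold = config$regression$positivity_threshold,
                      seed = seed, plotFile = file.path(out, "elbow.png"))
  path <- file.path(out, "elbow.csv")
  write.csv(curve, path, row.names = FALSE)
  .writeManifest(config, "elbow",
                 .stagePath(config, "embed", "latents.csv"), path, seed)
}

.stageFitDynamics <- function(config, out, seed) {
  scores <- .scoresTable(config)
  dy <- config$dynamics
  vel <- finiteDifferenceVelocities(scores, evaluation = dy$evaluation,
                                    minDt = dy$min_dt)
  field <- fitVelocityField(vel, restarts = dy$restarts, seed = seed)
  vPath <- file.path(out, "velocities.csv")
  write.csv(vel, vPath, row.names = FALSE)
  fPath <- file.path(out, "velocity_field.rds")
  saveRDS(field, fPath)
  .writeManifest(config, "fit-dynamics",
                 .stagePath(config, "fit-pca", "pca.json"),
                 c(vPath, fPath), seed)
}

.stageForecast <- function(config, out, seed) {
  field <- readRDS(.requireArtifact(
    .stagePath(config, "fit-dynamics", "velocity_field.rds"),
    "fit-dynamics"))
  scores <- .scoresTable(config)
  fc <- config$forecast
  base <- scores[order(scores$subject_id, scores$scan_time_years), ]
  base <- base[!duplicated(base$subject_id), ]
  cols <- field@scoreCols
  rows <- lapply(seq_len(nrow(base)), function(i) {
    tr <- integrateTrajectory(as.numeric(base[i, cols]),
                              c(age = base$age[i],
                                apoe4_count = base$apoe4_count[i]),
                              fc$horizon_years, h = fc$h, model = field)
    df <- data.frame(subject_id = base$subject_id[i], time = tr@times)
    df[cols] <- as.data.frame(tr@states)
    df
  })
  path <- file.path(out, "trajectories.csv")
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  .writeManifest(config, "forecast",
                 .stagePath(config, "fit-dynamics", "velocity_field.rds"),
                 path, seed)
}

.stageRender <- function(config, out, seed) {
  enc <- loadCheckpoint(.requireArtifact(
    .stagePath(config, "train-encoder", "encoder.rds"), "train-encoder"))
  gan <- loadCheckpoint(.requireArtifact(
    .stagePath(config, "train-gan", "gan.rds"), "train-gan"))
  pca <- .readPca(config)
  field <- readRDS(.requireArtifact(
    .stagePath(config, "fit-dynamics", "velocity_field.rds"),
    "fit-dynamics"))
  dat <- .loadCohortVolumes(config)
  rd <- config$render
  sid <- rd$subject %||% dat$cohort$subject_id[1L]
  row <- dat$cohort[dat$cohort$subject_id == sid, ][1L, ]
  idx <- which(dat$cohort$subject_id == sid)[1L]
  traj <- generateImageTrajectory(
    dat$volumes[[idx]], c(age = row$age, apoe4_count = row$apoe4_count),
    rd$times, enc, gan, pca, field, h = rd$h)
  spec <- dat$spec
  outputs <- character()
  for (i in seq_along(traj$times)) {
    p <- file.path(out, sprintf("%s_t%04.1fy.nii", sid, traj$times[i]))
    RNifti::writeNifti(.asNifti(traj$volumes[[i]], spec), p)
    outputs <- c(outputs, p)
  }
  pngPath <- file.path(out, "difference_panels.png")
  if (capabilities("png")) {
    .renderDifferencePanels(traj, rd$window, pngPath)
    outputs <- c(outputs, pngPath)
  }
  .writeManifest(config, "render-trajectory",
                 .stagePath(config, "fit-dynamics", "velocity_field.rds"),
                 outputs, seed)
}

# Axial mid-slice panels: rendered volumes on top, differences from the
# baseline rendering (symmetric color window) below.
.renderDifferencePanels <- function(traj, window, path) {
  n <- length(traj$times)
  grDevices::png(path, width = 220 * n, height = 440)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, n), mar = c(1, 1, 2, 1))
  zmid <- ceiling(dim(traj$volumes[[1L]])[3L] / 2)
  for (i in seq_len(n)) {
    graphics::image(traj$volumes[[i]][, , zmid], axes = FALSE,
                    col = grDevices::gray.colors(128, 0, 1),
                    main = sprintf("t = %g y", traj$times[i]))
  }
  divPal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(128)
  for (i in seq_len(n)) {
    graphics::image(pmin(pmax(traj$differences[[i]][, , zmid], window[1L]),
                         window[2L]),
                    zlim = window, axes = FALSE, col = divPal,
                    main = sprintf("difference t = %g y", traj$times[i]))
  }
  invisible(path)
}

.stagePlot <- function(config, out, seed) {
  field <- readRDS(.requireArtifact(
    .stagePath(config, "fit-dynamics", "velocity_field.rds"),
    "fit-dynamics"))
  scores <- .scoresTable(config)
  pl <- config$plot
  path <- file.path(out, "dynamics.png")
  plotDynamics(scores, field, pcPair = pl$pc_pair,
               shortYears = pl$short_years,
               longSubjects = pl$long_subjects %||% character(),
               longYears = pl$long_years, file = path,
               h = config$render$h)
  outs <- if (file.exists(path)) path else character()
  .writeManifest(config, "plot-dynamics",
                 .stagePath(config, "fit-dynamics", "velocity_field.rds"),
                 outs, seed)
}
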