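# Synthetic phantom-brain cohorts with known amyloid dynamics.
#
# A phantom volume is an ellipsoidal "cortical" shell around a central
# "ventricle" cavity, with a separate "cerebellum" ellipsoid low in the
# grid serving as the reference region. Tracer uptake in the cortex is an
# affine function of the latent amyloid load a(t); the cerebellum is held
# at a fixed reference intensity, so the cortex/cerebellum intensity ratio
# (the SUVR) equals suvrOffset + suvrSlope * a by construction.

#' @rdname phantomSpec
#' @export
setClass("PhantomSpec", representation(
  gridShape       = "integer",
  voxelSizeMm     = "numeric",
  cortexCenter    = "numeric",
  cortexOuterRadius = "numeric",
  cortexInnerRadius = "numeric",
  cerebellumCenter = "numeric",
  cerebellumRadius = "numeric",
  ventricleCenter = "numeric",
  ventricleRadius = "numeric",
  background      = "numeric",
  referenceValue  = "numeric",
  noiseSigma      = "numeric",
  seed            = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape <= 0L))
    msg <- c(msg, "gridShape must be three positive integers")
  if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be positive")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be nonnegative")
  if (length(msg) == 0L) {
    m <- phantomMasks(object, check = TRUE)
    if (inherits(m, "character")) msg <- c(msg, m)
    else {
      if (!any(m$reference)) msg <- c(msg, "cerebellum (reference) mask is empty")
      if (!any(m$cortex)) msg <- c(msg, "cortex mask is empty")
      if (any(m$cortex & m$reference) || any(m$cortex & m$ventricles) ||
          any(m$reference & m$ventricles))
        msg <- c(msg, "region masks must be disjoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Phantom geometry and acquisition specification
#'
#' Defines the voxel grid, the ellipsoidal region geometry (cortical shell,
#' cerebellar reference region, ventricles) and the additive acquisition
#' noise of the phantom generator. Default geometry scales with the grid so
#' the same relative anatomy is produced at any resolution; the full-scale
#' profile is a 160 x 160 x 96 grid of 1.5 mm cubic voxels.
#'
#' @param gridShape three positive integers, voxels per axis.
#' @param voxelSizeMm edge length of the cubic voxels, millimetres.
#' @param noiseSigma standard deviation of additive white acquisition noise,
#'   in units of the reference-region intensity.
#' @param seed integer seed controlling any randomness tied to the spec.
#' @param cortexCenter,cortexOuterRadius,cortexInnerRadius ellipsoid centre
#'   and radii (voxel units) of the cortical shell.
#' @param cerebellumCenter,cerebellumRadius reference-region ellipsoid.
#' @param ventricleCenter,ventricleRadius central cavity ellipsoid.
#' @param background intensity of non-region brain tissue, as a fraction of
#'   the reference value.
#' @param referenceValue mean intensity of the reference region.
#' @return a `PhantomSpec` object.
#' @examples
#' spec <- phantomSpec(gridShape = c(16, 16, 16), noiseSigma = 0)
#' vol <- buildPhantom(spec, load = 0.5, seed = 1)
#' computeReferenceSuvr(vol, phantomMasks(spec))
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 24L), voxelSizeMm = 1.5,
                        noiseSigma = 0.02, seed = 1L,
                        cortexCenter = NULL, cortexOuterRadius = NULL,
                        cortexInnerRadius = NULL,
                        cerebellumCenter = NULL, cerebellumRadius = NULL,
                        ventricleCenter = NULL, ventricleRadius = NULL,
                        background = 0.55, referenceValue = 1.0) {
  d <- as.integer(round(gridShape))
  ctr <- (d + 1) / 2
  # cortex occupies the upper ~2/3 of the grid; cerebellum sits below it
  cortexCenter <- cortexCenter %||% c(ctr[1], ctr[2], ctr[3] + 0.10 * d[3])
  cortexOuterRadius <- cortexOuterRadius %||% (c(0.40, 0.40, 0.28) * d)
  cortexInnerRadius <- cortexInnerRadius %||% (c(0.28, 0.28, 0.19) * d)
  ventricleCenter <- ventricleCenter %||% cortexCenter
  ventricleRadius <- ventricleRadius %||% (c(0.10, 0.10, 0.07) * d)
  cerebellumCenter <- cerebellumCenter %||% c(ctr[1], ctr[2], 0.16 * d[3])
  cerebellumRadius <- cerebellumRadius %||% (c(0.22, 0.22, 0.09) * d)
  new("PhantomSpec", gridShape = d, voxelSizeMm = voxelSizeMm,
      cortexCenter = cortexCenter, cortexOuterRadius = cortexOuterRadius,
      cortexInnerRadius = cortexInnerRadius,
      cerebellumCenter = cerebellumCenter, cerebellumRadius = cerebellumRadius,
      ventricleCenter = ventricleCenter, ventricleRadius = ventricleRadius,
      background = background, referenceValue = referenceValue,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "),
      "voxels @", object@voxelSizeMm, "mm; noise sigma",
      object@noiseSigma, "\n")
})

.ellipsoidMask <- function(d, center, radius) {
  gx <- rep.int(seq_len(d[1]), d[2] * d[3])
  gy <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  gz <- rep(seq_len(d[3]), each = d[1] * d[2])
  q <- ((gx - center[1]) / radius[1])^2 + ((gy - center[2]) / radius[2])^2 +
       ((gz - center[3]) / radius[3])^2
  array(q <= 1, dim = d)
}

.checkInside <- function(d, center, radius, name) {
  if (any(center - radius < 0.5) || any(center + radius > d + 0.5))
    sprintf("region '%s' exceeds the %s grid", name, paste(d, collapse = "x"))
  else NULL
}

#' Region masks of a phantom
#'
#' @param spec a [phantomSpec()].
#' @param jitter optional numeric vector perturbing centres/radii (fractional,
#'   as produced internally by [buildPhantom()]'s anatomy jitter).
#' @param check internal: return error strings instead of stopping.
#' @return list with logical arrays `cortex`, `reference`, `ventricles`.
#' @export
phantomMasks <- function(spec, jitter = NULL, check = FALSE) {
  d <- spec@gridShape
  geo <- list(
    cortexCenter = spec@cortexCenter,
    cortexOuterRadius = spec@cortexOuterRadius,
    cortexInnerRadius = spec@cortexInnerRadius,
    cerebellumCenter = spec@cerebellumCenter,
    cerebellumRadius = spec@cerebellumRadius,
    ventricleCenter = spec@ventricleCenter,
    ventricleRadius = spec@ventricleRadius)
  if (!is.null(jitter)) {
    stopifnot(length(jitter) == length(unlist(geo)))
    geo <- relistParams(unlist(geo) * (1 + jitter), geo)
  }
  errs <- c(
    .checkInside(d, geo$cortexCenter, geo$cortexOuterRadius, "cortex"),
    .checkInside(d, geo$cerebellumCenter, geo$cerebellumRadius, "cerebellum"),
    .checkInside(d, geo$ventricleCenter, geo$ventricleRadius, "ventricles"))
  if (length(errs)) {
    if (check) return(errs)
    stop(paste(errs, collapse = "; "))
  }
  outer_ <- .ellipsoidMask(d, geo$cortexCenter, geo$cortexOuterRadius)
  inner_ <- .ellipsoidMask(d, geo$cortexCenter, geo$cortexInnerRadius)
  vent <- .ellipsoidMask(d, geo$ventricleCenter, geo$ventricleRadius)
  cereb <- .ellipsoidMask(d, geo$cerebellumCenter, geo$cerebellumRadius)
  cortex <- outer_ & !inner_
  cereb <- cereb & !outer_   # keep regions disjoint under jitter
  vent <- vent & inner_
  list(cortex = cortex, reference = cereb, ventricles = vent,
       interior = inner_ & !vent)
}

#' Ground-truth amyloid dynamics of the phantom cohort
#'
#' Amyloid load follows a logistic accumulation law
#' `da/dt = r * m^apoe4 * a * (1 - a / aMax)`, saturating at the carrying
#' capacity `aMax`; each APOE-e4 allele multiplies the base rate by the
#' allele multiplier. The true SUVR is affine in load:
#' `SUVR(a) = suvrOffset + suvrSlope * a`.
#'
#' @param baseRate logistic growth rate per year for non-carriers.
#' @param aMax carrying capacity of the amyloid load.
#' @param apoeMultiplier rate multiplier per APOE-e4 allele.
#' @param suvrOffset,suvrSlope the affine load-to-SUVR map; the offset is the
#'   SUVR of a load-free brain and must be positive.
#' @return a `GroundTruthDynamics` object.
#' @export
groundTruthDynamics <- function(baseRate = 0.25, aMax = 1.0,
                                apoeMultiplier = 1.5,
                                suvrOffset = 1.0, suvrSlope = 1.0) {
  new("GroundTruthDynamics", baseRate = baseRate, aMax = aMax,
      apoeMultiplier = apoeMultiplier, suvrOffset = suvrOffset,
      suvrSlope = suvrSlope)
}

#' @rdname groundTruthDynamics
#' @export
setClass("GroundTruthDynamics", representation(
  baseRate = "numeric", aMax = "numeric", apoeMultiplier = "numeric",
  suvrOffset = "numeric", suvrSlope = "numeric"))

setValidity("GroundTruthDynamics", function(object) {
  msg <- character()
  if (object@baseRate < 0) msg <- c(msg, "baseRate must be >= 0")
  if (object@aMax <= 0) msg <- c(msg, "aMax must be > 0")
  if (object@apoeMultiplier <= 0) msg <- c(msg, "apoeMultiplier must be > 0")
  if (object@suvrOffset <= 0) msg <- c(msg, "suvrOffset must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruthDynamics", function(object) {
  cat(sprintf(
    "GroundTruthDynamics: da/dt = %.3g * %.3g^apoe * a (1 - a/%.3g); SUVR = %.3g + %.3g a\n",
    object@baseRate, object@apoeMultiplier, object@aMax,
    object@suvrOffset, object@suvrSlope))
})

#' True SUVR of a given amyloid load
#' @param dynamics a [groundTruthDynamics()].
#' @param load amyloid load value(s).
#' @export
trueSuvr <- function(dynamics, load) dynamics@suvrOffset + dynamics@suvrSlope * load

#' Render one phantom PET volume at a given amyloid load
#'
#' @param spec a [phantomSpec()].
#' @param load amyloid load in `[0, aMax]`.
#' @param dynamics a [groundTruthDynamics()] supplying the load-to-SUVR map.
#' @param anatomyJitter standard deviation of the per-subject fractional
#'   perturbation of region centres/radii (0 = canonical anatomy).
#' @param seed integer seed; the volume is deterministic given the seed.
#' @return a 3D numeric array of shape `gridShape` with attribute
#'   `voxelSizeMm`.
#' @export
buildPhantom <- function(spec, load, dynamics = groundTruthDynamics(),
                         anatomyJitter = 0, seed = spec@seed) {
  if (load < 0 || load > dynamics@aMax)
    stop("load must lie in [0, aMax] = [0, ", dynamics@aMax, "]")
  withSeed(seed, {
    # jitter truncated at 2 sd so perturbed anatomy stays inside the grid
    jit <- if (anatomyJitter > 0)
      pmin(pmax(rnorm(21L, sd = anatomyJitter), -2 * anatomyJitter),
           2 * anatomyJitter) else NULL
    masks <- phantomMasks(spec, jitter = jit)
    d <- spec@gridShape
    ref <- spec@referenceValue
    vol <- array(0, dim = d)
    vol[masks$interior] <- spec@background * ref
    vol[masks$cortex] <- ref * trueSuvr(dynamics, load)
    vol[masks$reference] <- ref
    vol[masks$ventricles] <- 0
    if (spec@noiseSigma > 0)
      vol <- vol + array(rnorm(prod(d), sd = spec@noiseSigma * ref), dim = d)
    attr(vol, "voxelSizeMm") <- spec@voxelSizeMm
    vol
  })
}

#' Cortical-to-reference intensity ratio (ground-truth SUVR oracle)
#'
#' The mean intensity over the cortical mask divided by the mean over the
#' reference-region mask. Applied to a noiseless phantom it recovers the
#' affine load-to-SUVR map exactly; applied to rendered or reconstructed
#' volumes it serves as the independent SUVR read-out.
#'
#' @param volume a 3D numeric array.
#' @param masks list with logical arrays `cortex` and `reference` (as from
#'   [phantomMasks()]).
#' @return positive scalar SUVR.
#' @export
computeReferenceSuvr <- function(volume, masks) {
  for (nm in c("cortex", "reference")) {
    if (!any(masks[[nm]]))
      stop("mask '", nm, "' is empty")
  }
  refMean <- mean(volume[masks$reference])
  if (!is.finite(refMean) || refMean == 0)
    stop("reference region mean is zero or non-finite ('reference')")
  mean(volume[masks$cortex]) / refMean
}

# logistic closed form; used by tests and by forecasting oracles
logisticLoad <- function(a0, rate, aMax, t) {
  if (a0 <= 0) return(rep(0, length(t)))
  aMax / (1 + (aMax / a0 - 1) * exp(-rate * t))
}

#' Simulate a longitudinal phantom cohort
#'
#' Draws per-subject covariates (age, APOE-e4 allele count), a baseline
#' amyloid load and a per-subject rate multiplier, evolves the load under
#' the logistic ground-truth law with a fine-step reference integrator
#' (deSolve), renders one phantom volume per visit, and writes the scan
#' metadata CSV plus a ground-truth JSON sidecar.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param dynamics a [groundTruthDynamics()].
#' @param spec a [phantomSpec()].
#' @param outDir directory for NIfTI volumes and metadata (created).
#' @param visitCountProbs probabilities of 1..4 scans per subject; the
#'   default gives a mean of about 2.3 scans per subject.
#' @param visitInterval nominal spacing of visits in years; actual intervals
#'   get uniform jitter of `visitJitter` years.
#' @param visitJitter half-width of the uniform jitter on visit intervals.
#' @param anatomyJitter per-subject anatomy perturbation (see
#'   [buildPhantom()]).
#' @param rateSdLog lognormal sd of the per-subject rate multiplier.
#' @param seed integer seed; the cohort (CSV and volumes) is byte-reproducible
#'   given the seed.
#' @param writeVolumes write NIfTI files (set `FALSE` to keep volumes only in
#'   memory).
#' @return a list with `cohort` (data.frame: subject_id, scan_time_years, age,
#'   apoe4_count, suvr, diagnosis, nifti_path, true_load), `volumes` (list of
#'   arrays), `truth` (ground-truth parameters incl. per-subject rates),
#'   `dir`.
#' @export
simulateCohort <- function(nSubjects, dynamics = groundTruthDynamics(),
                           spec = phantomSpec(), outDir = tempfile("cohort"),
                           visitCountProbs = c(0.25, 0.35, 0.25, 0.15),
                           visitInterval = 1.0, visitJitter = 0.25,
                           anatomyJitter = 0.03, rateSdLog = 0.3,
                           seed = 1L, writeVolumes = TRUE) {
  stopifnot(nSubjects >= 1)
  if (writeVolumes) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  withSeed(seed, {
    rows <- list()
    volumes <- list()
    truthSubjects <- list()
    for (i in seq_len(nSubjects)) {
      sid <- sprintf("S%03d", i)
      apoe <- sample(0:2, 1L, prob = c(0.55, 0.33, 0.12))
      age0 <- round(rnorm(1, 73, 6), 1)
      a0 <- dynamics@aMax * stats::rbeta(1, 1.2, 2.2)
      rateMult <- exp(rnorm(1, 0, rateSdLog))
      rate <- dynamics@baseRate * dynamics@apoeMultiplier^apoe * rateMult
      nVisits <- sample(seq_along(visitCountProbs), 1L, prob = visitCountProbs)
      gaps <- visitInterval + runif(max(nVisits - 1L, 0L), -visitJitter, visitJitter)
      times <- c(0, cumsum(gaps))[seq_len(nVisits)]
      loads <- .referenceLoadTrajectory(a0, rate, dynamics@aMax, times)
      diagnosis <- if (a0 < 0.12) "CN" else if (a0 < 0.45) "MCI" else "AD"
      jseed <- stageSeed(seed, paste0("subject:", sid))
      for (v in seq_len(nVisits)) {
        vseed <- stageSeed(jseed, paste0("visit:", v))
        vol <- buildPhantom(spec, loads[v], dynamics,
                            anatomyJitter = anatomyJitter, seed = vseed)
        fname <- sprintf("%s_v%d.nii", sid, v)
        if (writeVolumes)
          RNifti::writeNifti(.asNifti(vol, spec), file.path(outDir, fname))
        volumes[[fname]] <- vol
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, scan_time_years = times[v],
          age = age0 + times[v], apoe4_count = apoe,
          suvr = trueSuvr(dynamics, loads[v]), diagnosis = diagnosis,
          nifti_path = fname, true_load = loads[v],
          stringsAsFactors = FALSE)
      }
      truthSubjects[[sid]] <- list(a0 = a0, rate = rate, apoe4_count = apoe,
                                   rate_multiplier = rateMult,
                                   times = times, loads = loads)
    }
    cohort <- do.call(rbind, rows)
    truth <- list(
      dynamics = list(baseRate = dynamics@baseRate, aMax = dynamics@aMax,
                      apoeMultiplier = dynamics@apoeMultiplier,
                      suvrOffset = dynamics@suvrOffset,
                      suvrSlope = dynamics@suvrSlope),
      subjects = truthSubjects)
    if (writeVolumes) {
      write.csv(cohort, file.path(outDir, "cohort.csv"), row.names = FALSE)
      jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(cohort = cohort, volumes = volumes, truth = truth, dir = outDir,
         spec = spec, dynamics = dynamics)
  })
}

.asNifti <- function(vol, spec) {
  RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)),
                  pixdim = rep(spec@voxelSizeMm, 3L), datatype = "float")
}

# Reference integrator for the ground-truth logistic law (fine-step lsoda).
.referenceLoadTrajectory <- function(a0, rate, aMax, times) {
  if (length(times) == 1L && times[1] == 0) return(a0)
  tGrid <- sort(unique(c(0, times)))
  sol <- deSolve::ode(
    y = c(a = a0), times = tGrid,
    func = function(t, y, p) list(rate * y * (1 - y / aMax)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  sol[match(times, tGrid), "a"]
}
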