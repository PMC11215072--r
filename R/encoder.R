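# Inversion encoder: maps a PET volume to the intermediate latent vector w
# of a trained generator. Architecture (paper-scale default): five blocks of
# filtered (average-pool) downsampling followed by a 3x3x3 convolution with
# LReLU, filter depths 16/32/32/32/16, then a linear dense head of size 96.
# Trained by minimizing || PET - G(E(PET)) ||^2 with G frozen.

#' @rdname encoderConfig
#' @export
setClass("EncoderConfig", representation(
  inputShape = "integer", filterDepths = "integer", wDim = "integer",
  lr = "numeric", steps = "integer", batchSize = "integer",
  logEvery = "integer", syntheticFraction = "numeric",
  latentWeight = "numeric", seed = "integer"))

setValidity("EncoderConfig", function(object) {
  msg <- character()
  if (length(object@filterDepths) < 1L)
    msg <- c(msg, "at least one convolution block is required")
  if (any(object@inputShape %% (2L^length(object@filterDepths)) != 0L))
    msg <- c(msg, sprintf(
      "input shape (%s) not divisible by 2^%d",
      paste(object@inputShape, collapse = "x"), length(object@filterDepths)))
  if (length(msg)) msg else TRUE
})

#' Configuration of the inversion encoder
#'
#' If the grid does not allow the requested number of 2x downsampling blocks,
#' the block count is reduced automatically (keeping the leading filter
#' depths) with a warning; the paper-scale 160 x 160 x 96 profile always
#' supports the full five blocks.
#'
#' @param inputShape three integers, the input volume grid.
#' @param filterDepths integer vector of convolution filter depths, one per
#'   block.
#' @param wDim output latent dimension (must match the generator).
#' @param lr Adam learning rate.
#' @param steps,batchSize,logEvery training schedule.
#' @param syntheticFraction probability, per training sample, of drawing a
#'   freshly synthesized volume `G(M(z))` instead of a training scan. The
#'   loss is the same image-space MSE either way; on synthesized samples the
#'   true inverse is well defined, which anchors the encoder to the
#'   generator's own latent-to-image map and stabilizes inversion. 0 trains
#'   on real scans only.
#' @param latentWeight weight of an auxiliary latent-consistency term
#'   `mean((E(G(w)) - w)^2)` applied to synthesized samples only, where the
#'   generating `w` is known. 0 disables it; it has no effect when
#'   `syntheticFraction` is 0.
#' @param seed integer seed.
#' @return an `EncoderConfig`.
#' @export
encoderConfig <- function(inputShape = c(160L, 160L, 96L),
                          filterDepths = c(16L, 32L, 32L, 32L, 16L),
                          wDim = 96L, lr = 1e-3, steps = 300L,
                          batchSize = 4L, logEvery = 10L,
                          syntheticFraction = 0, latentWeight = 0,
                          seed = 1L) {
  inputShape <- as.integer(inputShape)
  filterDepths <- as.integer(filterDepths)
  maxBlocks <- 0L
  while (maxBlocks < length(filterDepths) &&
         all(inputShape %% (2L^(maxBlocks + 1L)) == 0L) &&
         all(inputShape %/% (2L^(maxBlocks + 1L)) >= 1L))
    maxBlocks <- maxBlocks + 1L
  if (maxBlocks < length(filterDepths)) {
    warning(sprintf(
      "grid %s supports only %d downsampling blocks; reducing from %d",
      paste(inputShape, collapse = "x"), maxBlocks, length(filterDepths)))
    filterDepths <- filterDepths[seq_len(maxBlocks)]
  }
  stopifnot(syntheticFraction >= 0, syntheticFraction <= 1)
  new("EncoderConfig", inputShape = inputShape, filterDepths = filterDepths,
      wDim = as.integer(wDim), lr = lr, steps = as.integer(steps),
      batchSize = as.integer(batchSize), logEvery = as.integer(logEvery),
      syntheticFraction = syntheticFraction, latentWeight = latentWeight,
      seed = as.integer(seed))
}

setMethod("show", "EncoderConfig", function(object) {
  cat("EncoderConfig:", paste(object@inputShape, collapse = " x "),
      "| blocks", paste(object@filterDepths, collapse = "/"),
      "| w", object@wDim, "\n")
})

#' @rdname encoderConfig
#' @export
setClass("EncoderModel", representation(
  config = "EncoderConfig", params = "list", step = "integer"))

setMethod("show", "EncoderModel", function(object) {
  cat("EncoderModel after", object@step, "training steps\n")
  show(object@config)
})

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "EncoderModel", function(x) x@config)
#' @rdname modelConfig
#' @export
setMethod("trainingStep", "EncoderModel", function(x) x@step)

#' Filter depths of the encoder's convolution blocks
#' @param config an `EncoderConfig` or `EncoderModel`.
#' @return integer vector, one depth per block.
#' @export
encoderFilterDepths <- function(config) {
  if (is(config, "EncoderModel")) config <- config@config
  config@filterDepths
}

.encShapes <- function(cfg) {
  lapply(seq_along(cfg@filterDepths),
         function(l) cfg@inputShape %/% (2L^l))
}

#' Initialize an untrained encoder
#'
#' @param config an [encoderConfig()].
#' @return an `EncoderModel` with `trainingStep(x) == 0`.
#' @export
initEncoder <- function(config) {
  withSeed(stageSeed(config@seed, "encoder-init"), {
    depths <- config@filterDepths
    cin <- 1L
    convs <- vector("list", length(depths))
    for (l in seq_along(depths)) {
      convs[[l]] <- list(W = heInit(27L * cin, depths[l]),
                         b = numeric(depths[l]))
      cin <- depths[l]
    }
    nflat <- prod(config@inputShape %/% (2L^length(depths))) *
             depths[length(depths)]
    dense <- list(W = heInit(nflat, config@wDim, gain = 1),
                  b = numeric(config@wDim))
    new("EncoderModel", config = config,
        params = list(convs = convs, dense = dense), step = 0L)
  })
}

.encForward <- function(par, cfg, x, cache = FALSE) {
  shapes <- .encShapes(cfg)
  nb <- length(cfg@filterDepths)
  caches <- if (cache) vector("list", nb)
  d <- cfg@inputShape
  for (l in seq_len(nb)) {
    xp <- avgPoolForward(x, d)
    dOut <- shapes[[l]]
    cf <- convForward(xp, dOut, par$convs[[l]]$W, par$convs[[l]]$b)
    lr <- lreluForward(cf$Y)
    if (cache) caches[[l]] <- list(P = cf$P, neg = lr$neg, dIn = d, dOut = dOut)
    x <- lr$Y
    d <- dOut
  }
  flat <- matrix(as.numeric(x), 1L)
  w <- denseForward(flat, par$dense$W, par$dense$b)   # linear head
  if (cache) caches$head <- list(flat = flat, xdim = dim(x))
  list(w = w, caches = caches)
}

.encBackward <- function(par, cfg, caches, dw) {
  hd <- caches$head
  bd <- denseBackward(dw, hd$flat, par$dense$W)
  dx <- matrix(bd$dx, hd$xdim[1L], hd$xdim[2L])
  depths <- cfg@filterDepths
  cins <- c(1L, depths[-length(depths)])
  gConvs <- vector("list", length(depths))
  for (l in rev(seq_along(depths))) {
    cc <- caches[[l]]
    dPre <- lreluBackward(dx, cc$neg)
    gc <- convBackward(dPre, cc$dOut, par$convs[[l]]$W, cc$P, cins[l])
    gConvs[[l]] <- list(W = gc$dW, b = gc$db)
    dx <- avgPoolBackward(gc$dX, cc$dIn)
  }
  list(grads = list(convs = gConvs, dense = list(W = bd$dW, b = bd$db)),
       dVol = dx)
}

#' Encode a volume into the intermediate latent space
#'
#' @param model an `EncoderModel`.
#' @param volume 3D array of the configured input shape.
#' @return numeric vector of length `wDim` (no output activation).
#' @export
encodeVolume <- function(model, volume) {
  cfg <- model@config
  if (!identical(as.integer(dim(volume)), cfg@inputShape))
    stop("volume has shape ", paste(dim(volume), collapse = "x"),
         " but encoder expects ", paste(cfg@inputShape, collapse = "x"))
  x <- matrix(as.numeric(volume), ncol = 1L)
  .encForward(model@params, cfg, x)$w
}

#' Normalize a volume by its reference-region mean
#'
#' Rescales intensities so the reference region has unit mean, making the
#' cortical signal a relative (SUVR-like) quantity before encoding.
#'
#' @param volume 3D numeric array.
#' @param referenceMask logical array of the same shape.
#' @return the rescaled array.
#' @export
normalizeVolume <- function(volume, referenceMask) {
  m <- mean(volume[referenceMask])
  if (!is.finite(m) || m == 0) stop("reference region mean is zero or non-finite")
  volume / m
}

#' Train the inversion encoder against a frozen generator
#'
#' Minimizes the mean squared voxel error of `G(E(x))` against `x` over the
#' training volumes; generator parameters receive no updates.
#'
#' @param volumes list of 3D arrays.
#' @param gan a trained `GanModel` (its `wDim` must match the encoder's).
#' @param config an [encoderConfig()].
#' @param init optional `EncoderModel` to resume from.
#' @return list with `model` (an `EncoderModel`) and `log` (data.frame:
#'   step, loss).
#' @export
trainEncoder <- function(volumes, gan, config, init = NULL) {
  stopifnot(length(volumes) > 0L)
  gcfg <- gan@config
  if (config@wDim != gcfg@wDim)
    stop("encoder wDim (", config@wDim, ") does not match generator wDim (",
         gcfg@wDim, ")")
  if (!identical(config@inputShape, gcfg@volumeShape))
    stop("encoder input shape does not match generator volume shape")
  model <- init %||% initEncoder(config)
  xs <- lapply(volumes, .volAsMatrix, cfg = gcfg)
  theta <- flattenParams(model@params)
  skel <- model@params
  state <- adamInit(length(theta))
  gen <- gan@params$generator
  noise <- gan@buffers$noise
  nvox <- prod(gcfg@volumeShape)
  log <- list()
  withSeed(stageSeed(config@seed, "encoder-train"), {
    for (step in seq_len(config@steps)) {
      par <- relistParams(theta, skel)
      gE <- NULL; loss <- 0
      for (b in seq_len(config@batchSize)) {
        wTrue <- NULL
        x <- if (config@syntheticFraction > 0 &&
                 runif(1) < config@syntheticFraction) {
          wTrue <- .mappingForward(gan@params$mapping, rnorm(gcfg@zDim))$w
          .genForward(gen, noise, gcfg, wTrue)$Y
        } else {
          xs[[sample.int(length(xs), 1L)]]
        }
        fe <- .encForward(par, config, x, cache = TRUE)
        fg <- .genForward(gen, noise, gcfg, fe$w, cache = TRUE)
        resid <- fg$Y - x
        loss <- loss + mean(resid^2)
        dVol <- 2 * resid / nvox
        dw <- .genBackward(gen, noise, gcfg, fe$w, fg$caches, dVol,
                           paramGrads = FALSE)$dw
        if (!is.null(wTrue) && config@latentWeight > 0) {
          loss <- loss + config@latentWeight * mean((fe$w - wTrue)^2)
          dw <- dw + config@latentWeight * 2 * (fe$w - wTrue) / gcfg@wDim
        }
        gE <- .accumulate(gE, .encBackward(par, config, fe$caches, dw)$grads,
                          1 / config@batchSize)
      }
      loss <- loss / config@batchSize
      if (!is.finite(loss)) stop("non-finite reconstruction loss at step ", step)
      up <- adamStep(theta, gE, state, config@lr, beta1 = 0.9)
      theta <- up$theta; state <- up$state
      if (step %% config@logEvery == 0L || step == config@steps || step == 1L) {
        log[[length(log) + 1L]] <- data.frame(step = step, loss = loss)
      }
    }
  })
  model@params <- relistParams(theta, skel)
  model@step <- model@step + config@steps
  logDf <- if (length(log)) do.call(rbind, log)
           else data.frame(step = integer(), loss = numeric())
  list(model = model, log = logDf)
}

#' Reconstruct a volume through the encoder and generator
#'
#' @param volume 3D array.
#' @param encoder an `EncoderModel`.
#' @param gan a `GanModel`.
#' @return `G(E(volume))`, same shape as the input.
#' @export
reconstructVolume <- function(volume, encoder, gan) {
  synthesize(gan, encodeVolume(encoder, volume))
}
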