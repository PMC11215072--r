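# 3D style-based generative adversarial network.
#
# A mapping network M (fully connected MLP) embeds z ~ N(0, I) into the
# intermediate latent space W; the synthesis network G starts from a learned
# constant grid and applies successive upsample + 3x3x3 convolution blocks,
# each modulated per-channel by an affine transform of w (the "style") and
# perturbed by fixed, seeded per-level noise; a convolutional discriminator D
# scores volumes. Training uses the non-saturating logistic loss with a
# zero-centred gradient penalty on real samples.

#' @rdname ganConfig
#' @export
setClass("GanConfig", representation(
  volumeShape = "integer", zDim = "integer", wDim = "integer",
  mappingDepth = "integer", levels = "integer", channels = "integer",
  dHidden = "integer", lrG = "numeric", lrD = "numeric",
  r1Weight = "numeric", steps = "integer", batchSize = "integer",
  logEvery = "integer", seed = "integer"))

setValidity("GanConfig", function(object) {
  msg <- character()
  if (object@mappingDepth < 1L) msg <- c(msg, "mappingDepth must be >= 1")
  if (length(object@channels) != object@levels + 1L)
    msg <- c(msg, "channels must have length levels + 1")
  if (any(object@volumeShape %% (2L^object@levels) != 0L))
    msg <- c(msg, sprintf(
      "each axis of volumeShape (%s) must be divisible by 2^levels = %d",
      paste(object@volumeShape, collapse = "x"), 2L^object@levels))
  if (length(msg)) msg else TRUE
})

#' Configuration of the 3D style-based GAN
#'
#' The paper-scale default targets 160 x 160 x 96 volumes with a 96-dim
#' latent space and an 8-layer mapping network; that profile is GPU-scale
#' and meant for introspection or off-line training. [tinyGanConfig()] gives
#' a CPU-trainable profile used throughout the test-scale pipeline.
#'
#' @param volumeShape three integers, the output grid.
#' @param zDim,wDim input-noise and intermediate latent dimensions.
#' @param mappingDepth number of fully connected layers in the mapping MLP.
#' @param levels number of 2x upsampling levels in the synthesis network.
#' @param channels integer vector of length `levels + 1`: channel counts at
#'   the constant base grid and after each level's convolution.
#' @param dHidden width of the discriminator's dense hidden layer.
#' @param lrG,lrD Adam learning rates of generator(+mapping) and
#'   discriminator.
#' @param r1Weight weight of the gradient penalty on real samples.
#' @param steps,batchSize,logEvery training schedule.
#' @param seed integer seed controlling initialization, fixed per-level
#'   noise, and the training stream.
#' @return a `GanConfig`.
#' @export
ganConfig <- function(volumeShape = c(160L, 160L, 96L), zDim = 96L,
                      wDim = 96L, mappingDepth = 8L, levels = 5L,
                      channels = c(64L, 64L, 48L, 32L, 24L, 16L),
                      dHidden = 64L, lrG = 2e-3, lrD = 2e-3,
                      r1Weight = 1.0, steps = 2000L, batchSize = 4L,
                      logEvery = 10L, seed = 1L) {
  new("GanConfig", volumeShape = as.integer(volumeShape),
      zDim = as.integer(zDim), wDim = as.integer(wDim),
      mappingDepth = as.integer(mappingDepth), levels = as.integer(levels),
      channels = as.integer(channels), dHidden = as.integer(dHidden),
      lrG = lrG, lrD = lrD, r1Weight = r1Weight, steps = as.integer(steps),
      batchSize = as.integer(batchSize), logEvery = as.integer(logEvery),
      seed = as.integer(seed))
}

#' @rdname ganConfig
#' @param ... overrides passed to [ganConfig()].
#' @export
tinyGanConfig <- function(...) {
  defaults <- list(volumeShape = c(16L, 16L, 16L), zDim = 16L, wDim = 16L,
                   mappingDepth = 8L, levels = 2L, channels = c(12L, 12L, 8L),
                   dHidden = 32L, steps = 200L, batchSize = 4L, seed = 1L)
  do.call(ganConfig, modifyList(defaults, list(...)))
}

setMethod("show", "GanConfig", function(object) {
  cat("GanConfig:", paste(object@volumeShape, collapse = " x "),
      "| z", object@zDim, "-> w", object@wDim,
      "| mapping depth", object@mappingDepth,
      "| levels", object@levels,
      "| channels", paste(object@channels, collapse = "/"), "\n")
})

#' @rdname ganModel
#' @export
setClass("GanModel", representation(
  config = "GanConfig", params = "list", buffers = "list", step = "integer"))

setMethod("show", "GanModel", function(object) {
  cat("GanModel after", object@step, "training steps\n")
  show(object@config)
})

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "GanModel", function(x) x@config)
#' @rdname modelConfig
#' @export
setMethod("trainingStep", "GanModel", function(x) x@step)

.baseShape <- function(cfg) cfg@volumeShape %/% (2L^cfg@levels)

.levelShapes <- function(cfg) {
  b <- .baseShape(cfg)
  lapply(0:cfg@levels, function(l) b * 2L^l)
}

#' Initialize an untrained GAN
#'
#' Builds mapping, generator and discriminator parameters plus the fixed
#' per-level noise buffers from the config's seed.
#'
#' @param config a [ganConfig()].
#' @return a `GanModel` with `trainingStep(x) == 0`.
#' @export
initGan <- function(config) {
  withSeed(stageSeed(config@seed, "gan-init"), {
    shapes <- .levelShapes(config)
    ch <- config@channels
    mapping <- vector("list", config@mappingDepth)
    nin <- config@zDim
    for (l in seq_len(config@mappingDepth)) {
      mapping[[l]] <- list(W = heInit(nin, config@wDim), b = numeric(config@wDim))
      nin <- config@wDim
    }
    levels <- vector("list", config@levels)
    for (l in seq_len(config@levels)) {
      cin <- ch[l]; cout <- ch[l + 1L]
      # style maps start small but nonzero so the synthesis depends on w
      # from the first step (a zero init would leave G blind to w until
      # adversarial gradients build the dependence from scratch)
      levels[[l]] <- list(
        W = heInit(27L * cin, cout), b = numeric(cout),
        S = matrix(rnorm(config@wDim * cout, sd = 0.2 / sqrt(config@wDim)),
                   config@wDim, cout),
        B = matrix(rnorm(config@wDim * cout, sd = 0.2 / sqrt(config@wDim)),
                   config@wDim, cout),
        strength = numeric(cout))
    }
    generator <- list(
      const = matrix(rnorm(prod(shapes[[1L]]) * ch[1L]), prod(shapes[[1L]]), ch[1L]),
      levels = levels,
      final = list(W = heInit(27L * ch[config@levels + 1L], 1L, gain = 1),
                   b = numeric(1L)))
    noise <- lapply(seq_len(config@levels),
                    function(l) rnorm(prod(shapes[[l + 1L]])))
    dch <- c(1L, rev(ch[-1L]))
    convs <- vector("list", config@levels)
    for (l in seq_len(config@levels)) {
      convs[[l]] <- list(W = heInit(27L * dch[l], dch[l + 1L]),
                         b = numeric(dch[l + 1L]))
    }
    nflat <- prod(shapes[[1L]]) * dch[config@levels + 1L]
    discriminator <- list(
      convs = convs,
      dense1 = list(W = heInit(nflat, config@dHidden), b = numeric(config@dHidden)),
      dense2 = list(W = heInit(config@dHidden, 1L, gain = 1), b = numeric(1L)))
    new("GanModel", config = config,
        params = list(mapping = mapping, generator = generator,
                      discriminator = discriminator),
        buffers = list(noise = noise), step = 0L)
  })
}

# ---- mapping network --------------------------------------------------------

.mappingForward <- function(mapping, z, cache = FALSE) {
  h <- as.numeric(z)
  caches <- if (cache) vector("list", length(mapping))
  for (l in seq_along(mapping)) {
    x <- h
    a <- denseForward(matrix(h, 1L), mapping[[l]]$W, mapping[[l]]$b)
    lr <- lreluForward(a)
    h <- lr$Y
    if (cache) caches[[l]] <- list(x = x, neg = lr$neg)
  }
  list(w = h, caches = caches)
}

.mappingBackward <- function(mapping, caches, dw) {
  grads <- vector("list", length(mapping))
  g <- dw
  for (l in rev(seq_along(mapping))) {
    g <- lreluBackward(g, caches[[l]]$neg)
    bk <- denseBackward(g, caches[[l]]$x, mapping[[l]]$W)
    grads[[l]] <- list(W = bk$dW, b = bk$db)
    g <- bk$dx
  }
  list(grads = grads, dz = g)
}

#' Map input noise to the intermediate latent space
#'
#' @param model a `GanModel`.
#' @param z numeric vector of length `zDim`.
#' @return numeric vector `w` of length `wDim`.
#' @export
mapLatent <- function(model, z) {
  cfg <- model@config
  if (length(z) != cfg@zDim)
    stop("z has length ", length(z), " but zDim is ", cfg@zDim)
  .mappingForward(model@params$mapping, z)$w
}

# ---- generator --------------------------------------------------------------

.genForward <- function(gen, noise, cfg, w, cache = FALSE) {
  shapes <- .levelShapes(cfg)
  x <- gen$const
  caches <- if (cache) vector("list", cfg@levels)
  for (l in seq_len(cfg@levels)) {
    dPrev <- shapes[[l]]; dCur <- shapes[[l + 1L]]
    xu <- upsampleForward(x, dPrev)
    cf <- convForward(xu, dCur, gen$levels[[l]]$W, gen$levels[[l]]$b)
    h <- cf$Y
    s <- 1 + as.vector(w %*% gen$levels[[l]]$S)
    tt <- as.vector(w %*% gen$levels[[l]]$B)
    n <- nrow(h)
    h2 <- h * rep(s, each = n) + rep(tt, each = n)
    h3 <- h2 + outer(noise[[l]], gen$levels[[l]]$strength)
    lr <- lreluForward(h3)
    if (cache) caches[[l]] <- list(P = cf$P, h = h, s = s, neg = lr$neg)
    x <- lr$Y
  }
  cfF <- convForward(x, shapes[[cfg@levels + 1L]], gen$final$W, gen$final$b)
  if (cache) caches$final <- list(P = cfF$P, xin = x)
  list(Y = cfF$Y, caches = caches)
}

.genBackward <- function(gen, noise, cfg, w, caches, dY, paramGrads = TRUE) {
  shapes <- .levelShapes(cfg)
  ch <- cfg@channels
  gFinal <- convBackward(dY, shapes[[cfg@levels + 1L]], gen$final$W,
                         caches$final$P, ch[cfg@levels + 1L], paramGrads)
  dx <- gFinal$dX
  dw <- numeric(cfg@wDim)
  gLevels <- vector("list", cfg@levels)
  for (l in rev(seq_len(cfg@levels))) {
    cc <- caches[[l]]
    dh3 <- lreluBackward(dx, cc$neg)
    dstrength <- as.vector(crossprod(dh3, noise[[l]]))
    dh2 <- dh3
    ds <- colSums(dh2 * cc$h)
    dt <- colSums(dh2)
    n <- nrow(dh2)
    dh <- dh2 * rep(cc$s, each = n)
    dw <- dw + as.vector(gen$levels[[l]]$S %*% ds) +
          as.vector(gen$levels[[l]]$B %*% dt)
    gConv <- convBackward(dh, shapes[[l + 1L]], gen$levels[[l]]$W, cc$P,
                          ch[l], paramGrads)
    if (paramGrads) {
      gLevels[[l]] <- list(W = gConv$dW, b = gConv$db, S = outer(w, ds),
                           B = outer(w, dt), strength = dstrength)
    }
    dx <- upsampleBackward(gConv$dX, shapes[[l]])
  }
  grads <- if (paramGrads)
    list(const = dx, levels = gLevels,
         final = list(W = gFinal$dW, b = gFinal$db))
  list(grads = grads, dw = dw)
}

#' Synthesize a volume from an intermediate latent vector
#'
#' Deterministic given the model: the per-level style noise is a fixed,
#' seeded buffer, so repeated synthesis of the same `w` is bit-identical.
#'
#' @param model a `GanModel`.
#' @param w numeric vector of length `wDim`.
#' @return 3D numeric array of shape `volumeShape`.
#' @export
synthesize <- function(model, w) {
  cfg <- model@config
  if (length(w) != cfg@wDim)
    stop("w has length ", length(w), " but wDim is ", cfg@wDim)
  y <- .genForward(model@params$generator, model@buffers$noise, cfg, w)$Y
  array(y, dim = cfg@volumeShape)
}

# ---- discriminator ----------------------------------------------------------

.volAsMatrix <- function(volume, cfg) {
  if (!identical(as.integer(dim(volume)), cfg@volumeShape))
    stop("volume has shape ", paste(dim(volume), collapse = "x"),
         " but config expects ", paste(cfg@volumeShape, collapse = "x"))
  matrix(as.numeric(volume), ncol = 1L)
}

.discForward <- function(disc, cfg, x, cache = FALSE) {
  shapes <- rev(.levelShapes(cfg))
  caches <- if (cache) vector("list", cfg@levels)
  dch <- c(1L, rev(cfg@channels[-1L]))
  for (l in seq_len(cfg@levels)) {
    d <- shapes[[l]]
    cf <- convForward(x, d, disc$convs[[l]]$W, disc$convs[[l]]$b)
    lr <- lreluForward(cf$Y)
    if (cache) caches[[l]] <- list(P = cf$P, neg = lr$neg, d = d)
    x <- avgPoolForward(lr$Y, d)
  }
  flat <- matrix(as.numeric(x), 1L)
  a1 <- denseForward(flat, disc$dense1$W, disc$dense1$b)
  lr1 <- lreluForward(a1)
  s <- denseForward(matrix(lr1$Y, 1L), disc$dense2$W, disc$dense2$b)
  if (cache) caches$head <- list(flat = flat, neg1 = lr1$neg, h1 = lr1$Y,
                                 xdim = dim(x))
  list(score = s, caches = caches)
}

.discBackward <- function(disc, cfg, caches, dScore, paramGrads = TRUE) {
  hd <- caches$head
  b2 <- denseBackward(dScore, matrix(hd$h1, 1L), disc$dense2$W, paramGrads)
  g1 <- lreluBackward(b2$dx, hd$neg1)
  b1 <- denseBackward(g1, hd$flat, disc$dense1$W, paramGrads)
  dx <- matrix(b1$dx, hd$xdim[1L], hd$xdim[2L])
  dch <- c(1L, rev(cfg@channels[-1L]))
  gConvs <- vector("list", cfg@levels)
  for (l in rev(seq_len(cfg@levels))) {
    cc <- caches[[l]]
    dUp <- avgPoolBackward(dx, cc$d)
    dPre <- lreluBackward(dUp, cc$neg)
    gc <- convBackward(dPre, cc$d, disc$convs[[l]]$W, cc$P, dch[l], paramGrads)
    if (paramGrads) gConvs[[l]] <- list(W = gc$dW, b = gc$db)
    dx <- gc$dX
  }
  grads <- if (paramGrads)
    list(convs = gConvs,
         dense1 = list(W = b1$dW, b = b1$db),
         dense2 = list(W = b2$dW, b = b2$db))
  list(grads = grads, dVol = dx)
}

#' Discriminator score of a volume
#'
#' @param model a `GanModel`.
#' @param volume 3D array of the configured shape.
#' @return finite scalar logit (higher = more "real").
#' @export
discriminate <- function(model, volume) {
  cfg <- model@config
  x <- .volAsMatrix(volume, cfg)
  .discForward(model@params$discriminator, cfg, x)$score
}

# ---- training ---------------------------------------------------------------

.accumulate <- function(acc, g, scale) {
  if (is.null(acc)) flattenParams(g) * scale else acc + flattenParams(g) * scale
}

#' Train the 3D style-based GAN
#'
#' Alternates one discriminator and one generator(+mapping) Adam step per
#' iteration, with the non-saturating logistic loss and a finite-difference
#' estimate of the zero-centred gradient penalty on real samples. Fully
#' seeded: two runs with the same data, config and seed give identical
#' parameters (single-threaded numerics).
#'
#' @param volumes list of 3D arrays, all of the configured shape.
#' @param config a [ganConfig()].
#' @param init optional `GanModel` to resume from; defaults to
#'   [initGan()] of `config`.
#' @return list with `model` (a `GanModel`) and `log` (data.frame:
#'   step, loss_G, loss_D).
#' @export
trainGan <- function(volumes, config, init = NULL) {
  stopifnot(length(volumes) > 0L)
  model <- init %||% initGan(config)
  cfg <- config
  xs <- lapply(volumes, .volAsMatrix, cfg = cfg)
  theta <- list(GM = flattenParams(model@params[c("mapping", "generator")]),
                D = flattenParams(model@params["discriminator"]))
  skel <- list(GM = model@params[c("mapping", "generator")],
               D = model@params["discriminator"])
  stateGM <- adamInit(length(theta$GM))
  stateD <- adamInit(length(theta$D))
  noise <- model@buffers$noise
  log <- list()
  nvox <- prod(cfg@volumeShape)
  fdEps <- 1e-3
  withSeed(stageSeed(cfg@seed, "gan-train"), {
    for (step in seq_len(cfg@steps)) {
      par <- relistParams(theta$GM, skel$GM)
      mapping <- par$mapping; gen <- par$generator
      disc <- relistParams(theta$D, skel$D)$discriminator
      B <- cfg@batchSize

      # ---- discriminator step
      gD <- NULL; lossD <- 0
      for (b in seq_len(B)) {
        z <- rnorm(cfg@zDim)
        w <- .mappingForward(mapping, z)$w
        fake <- .genForward(gen, noise, cfg, w)$Y
        real <- xs[[sample.int(length(xs), 1L)]]
        fwF <- .discForward(disc, cfg, fake, cache = TRUE)
        fwR <- .discForward(disc, cfg, real, cache = TRUE)
        lossD <- lossD + softplus(fwF$score) + softplus(-fwR$score)
        gF <- .discBackward(disc, cfg, fwF$caches, sigmoid(fwF$score))$grads
        gR <- .discBackward(disc, cfg, fwR$caches, -sigmoid(-fwR$score))$grads
        gD <- .accumulate(gD, gF, 1 / B)
        gD <- gD + flattenParams(gR) / B
        if (cfg@r1Weight > 0) {
          u <- rnorm(nvox)
          fwP <- .discForward(disc, cfg, real + fdEps * u, cache = TRUE)
          fwM <- .discForward(disc, cfg, real - fdEps * u, cache = TRUE)
          gHat <- (fwP$score - fwM$score) / (2 * fdEps)
          lossD <- lossD + cfg@r1Weight / 2 * gHat^2
          coefs <- cfg@r1Weight * gHat / (2 * fdEps)
          gP <- .discBackward(disc, cfg, fwP$caches, coefs)$grads
          gM <- .discBackward(disc, cfg, fwM$caches, -coefs)$grads
          gD <- gD + (flattenParams(gP) + flattenParams(gM)) / B
        }
      }
      lossD <- lossD / B
      if (!is.finite(lossD)) stop("non-finite discriminator loss at step ", step)
      up <- adamStep(theta$D, gD, stateD, cfg@lrD)
      theta$D <- up$theta; stateD <- up$state
      disc <- relistParams(theta$D, skel$D)$discriminator

      # ---- generator + mapping step
      gGM <- NULL; lossG <- 0
      for (b in seq_len(B)) {
        z <- rnorm(cfg@zDim)
        fm <- .mappingForward(mapping, z, cache = TRUE)
        fg <- .genForward(gen, noise, cfg, fm$w, cache = TRUE)
        fd <- .discForward(disc, cfg, fg$Y, cache = TRUE)
        lossG <- lossG + softplus(-fd$score)
        dScore <- -sigmoid(-fd$score)
        dVol <- .discBackward(disc, cfg, fd$caches, dScore,
                              paramGrads = FALSE)$dVol
        bg <- .genBackward(gen, noise, cfg, fm$w, fg$caches, dVol)
        bm <- .mappingBackward(mapping, fm$caches, bg$dw)
        gGM <- .accumulate(gGM, list(mapping = bm$grads, generator = bg$grads),
                           1 / B)
      }
      lossG <- lossG / B
      if (!is.finite(lossG)) stop("non-finite generator loss at step ", step)
      up <- adamStep(theta$GM, gGM, stateGM, cfg@lrG)
      theta$GM <- up$theta; stateGM <- up$state

      if (step %% cfg@logEvery == 0L || step == cfg@steps) {
        log[[length(log) + 1L]] <- data.frame(step = step, loss_G = lossG,
                                              loss_D = lossD)
      }
    }
  })
  par <- relistParams(theta$GM, skel$GM)
  model@params$mapping <- par$mapping
  model@params$generator <- par$generator
  model@params$discriminator <- relistParams(theta$D, skel$D)$discriminator
  model@step <- model@step + cfg@steps
  logDf <- if (length(log)) do.call(rbind, log)
           else data.frame(step = integer(), loss_G = numeric(),
                           loss_D = numeric())
  list(model = model, log = logDf)
}

# ---- checkpoints ------------------------------------------------------------

.configAsList <- function(cfg) {
  slots <- slotNames(class(cfg))
  out <- lapply(slots, function(s) slot(cfg, s))
  names(out) <- slots
  out
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single-archive serialization of the parameters, the
#' buffers, the training-step counter, and the configuration (also embedded
#' as JSON for external inspection). Round-trips are lossless.
#'
#' @param model a `GanModel` or `EncoderModel`.
#' @param path file path.
#' @export
saveCheckpoint <- function(model, path) {
  cfgList <- .configAsList(model@config)
  obj <- list(
    class = class(model)[1L],
    configJson = as.character(jsonlite::toJSON(cfgList, auto_unbox = TRUE,
                                               digits = NA)),
    config = model@config,
    params = model@params,
    buffers = if (.hasSlot(model, "buffers")) model@buffers else list(),
    step = model@step)
  saveRDS(obj, path)
  invisible(path)
}

.hasSlot <- function(x, name) name %in% slotNames(class(x))

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (obj$class == "GanModel") {
    new("GanModel", config = obj$config, params = obj$params,
        buffers = obj$buffers, step = obj$step)
  } else if (obj$class == "EncoderModel") {
    new("EncoderModel", config = obj$config, params = obj$params,
        step = obj$step)
  } else stop("unknown checkpoint class: ", obj$class)
}
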