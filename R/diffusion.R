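#' Build a forward-diffusion noise schedule
#'
#' Linear schedule: per-step variances `beta_t` interpolate `1e-4` to `0.02`
#' (the standard setting for `T = 1000`). Cosine schedule: `alphaBar_t`
#' follows the squared-cosine profile with offset `s = 0.008`, betas clipped
#' at 0.999.
#'
#' @param steps number of diffusion steps `T` (default 1000).
#' @param kind `"linear"` or `"cosine"`.
#' @return A [NoiseSchedule-class].
#' @export
noiseSchedule <- function(steps = 1000L, kind = c("linear", "cosine")) {
  kind <- match.arg(kind)
  stopifnot(steps >= 1L)
  if (kind == "linear") {
    beta <- seq(1e-4, 0.02, length.out = steps)
  } else {
    s <- 0.008
    f <- function(t) cos((t / steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:steps) / f(0)
    beta <- pmin(1 - ab[-1L] / ab[-(steps + 1L)], 0.999)
    beta <- pmax(beta, 1e-8)
  }
  alpha <- 1 - beta
  alphaBar <- cumprod(alpha)
  if (alphaBar[steps] >= 0.01)
    warning("terminal alphaBar is ", signif(alphaBar[steps], 3),
            " (>= 0.01): the forward process does not reach near-pure noise")
  new("NoiseSchedule", steps = as.integer(steps), beta = beta, alpha = alpha,
      alphaBar = alphaBar)
}

#' Forward noising (marginal sampling)
#'
#' Computes `z_t = sqrt(alphaBar_t) z_0 + sqrt(1 - alphaBar_t) eps` exactly.
#'
#' @param z0 clean latent: array whose first dimension indexes samples when
#'   `t` has length > 1, otherwise any numeric array.
#' @param t integer timestep(s) in `[1, T]` (scalar, or one per sample).
#' @param eps noise array, same shape as `z0`.
#' @param schedule a [NoiseSchedule-class].
#' @return `z_t`, same shape as `z0`.
#' @export
qSample <- function(z0, t, eps, schedule) {
  if (any(t < 1L) || any(t > schedule@steps)) stop("timestep out of range")
  if (!identical(dim(z0), dim(eps)) || length(z0) != length(eps))
    stop("z0 and eps shapes differ")
  ab <- schedule@alphaBar[t]
  if (length(ab) == 1L) return(sqrt(ab) * z0 + sqrt(1 - ab) * eps)
  d <- dim(z0)
  if (d[1L] != length(ab)) stop("length(t) must match the sample dimension")
  sab <- array(sqrt(ab), d)        # recycles along the first dimension
  snb <- array(sqrt(1 - ab), d)
  sab * z0 + snb * eps
}

#' Simple denoising objective
#'
#' Mean squared error between predicted and true noise (mean convention over
#' all elements).
#'
#' @param epsPred,eps arrays of identical shape.
#' @return Scalar loss.
#' @export
lossSimple <- function(epsPred, eps) {
  if (length(epsPred) != length(eps) || !identical(dim(epsPred), dim(eps)))
    stop("shape mismatch between predicted and true noise")
  mean((epsPred - eps)^2)
}

#' Classifier-free guidance combination
#'
#' Returns `(1 + omega) * epsCond - omega * epsUncond`; `omega = 0` returns
#' the conditional prediction unchanged.
#'
#' @param epsCond conditional noise prediction.
#' @param epsUncond unconditional (null-label) noise prediction, same shape.
#' @param omega guidance strength `>= 0`.
#' @return Guided noise prediction, same shape.
#' @export
cfgCombine <- function(epsCond, epsUncond, omega) {
  stopifnot(omega >= 0)
  if (length(epsCond) != length(epsUncond) ||
      !identical(dim(epsCond), dim(epsUncond)))
    stop("shape mismatch between conditional and unconditional predictions")
  (1 + omega) * epsCond - omega * epsUncond
}

#' One DDIM update step
#'
#' Predicts `z0` by inverting the forward marginal at `t`, then re-noises to
#' `tPrev`: with `eta = 0` the update is deterministic; `eta > 0` injects the
#' DDIM-scaled stochastic component.
#'
#' @param zt latent at timestep `t`.
#' @param epsTilde (guided) noise prediction at `t`, same shape.
#' @param t current timestep (`1 <= t <= T`).
#' @param tPrev target timestep (`0 <= tPrev < t`; 0 means the clean latent).
#' @param schedule a [NoiseSchedule-class].
#' @param eta stochasticity in `[0, 1]`.
#' @param noise optional fresh standard-normal array for `eta > 0`.
#' @return `z_{tPrev}`, same shape as `zt`.
#' @export
ddimStep <- function(zt, epsTilde, t, tPrev, schedule, eta = 0, noise = NULL) {
  if (!(t > tPrev && tPrev >= 0)) stop("invalid timestep pair: need t > tPrev >= 0")
  if (t > schedule@steps) stop("timestep out of range")
  stopifnot(eta >= 0, eta <= 1)
  abT <- schedule@alphaBar[t]
  abP <- if (tPrev == 0L) 1 else schedule@alphaBar[tPrev]
  z0hat <- (zt - sqrt(1 - abT) * epsTilde) / sqrt(abT)
  sigma <- eta * sqrt((1 - abP) / (1 - abT)) * sqrt(1 - abT / abP)
  out <- sqrt(abP) * z0hat + sqrt(pmax(1 - abP - sigma^2, 0)) * epsTilde
  if (sigma > 0) {
    if (is.null(noise)) noise <- array(stats::rnorm(length(zt)), dim(zt) %||% length(zt))
    out <- out + sigma * noise
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training configuration for the diffusion stage
#'
#' Defaults follow the reference training recipe: AdamW with fixed learning
#' rate `1e-4` and no weight decay, horizontal-flip augmentation, and an
#' exponential moving average of denoiser weights (decay 0.9999; shorter
#' desk-scale runs should shorten the EMA horizon to match, see the package
#' vignette).
#'
#' @param totalSteps optimization steps.
#' @param learningRate AdamW learning rate.
#' @param weightDecay decoupled weight decay (0 by default).
#' @param batchSize minibatch size.
#' @param emaDecay EMA decay rate in `[0, 1]`.
#' @param horizontalFlip augment latents with random horizontal flips.
#' @param trainSigma also train the covariance channels with a
#'   variational-bound term (stop-gradient on the mean); the simple noise
#'   MSE alone is the default objective.
#' @param sigmaWeight weight of the variational-bound term when enabled.
#' @param seed integer seed for all training randomness.
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(totalSteps = 2000L, learningRate = 1e-4,
                        weightDecay = 0, batchSize = 32L, emaDecay = 0.9999,
                        horizontalFlip = TRUE, trainSigma = FALSE,
                        sigmaWeight = 1e-3, seed = 1L) {
  stopifnot(learningRate > 0, emaDecay >= 0, emaDecay <= 1, batchSize >= 1,
            totalSteps >= 1)
  structure(list(totalSteps = as.integer(totalSteps),
                 learningRate = learningRate, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize), emaDecay = emaDecay,
                 horizontalFlip = horizontalFlip, trainSigma = trainSigma,
                 sigmaWeight = sigmaWeight, seed = as.integer(seed)),
            class = "TrainConfig")
}

# variational-bound term on the covariance channels: the model variance
# interpolates log-linearly between beta_t and the posterior variance
# betaTilde_t via v = sigmoid(raw channel); the mean is detached, so
# gradients flow only into the covariance head.
sigmaVlb <- function(sigmaRaw, epsPred, eps, t, schedule) {
  abT <- schedule@alphaBar[t]
  abPrev <- ifelse(t > 1L, schedule@alphaBar[pmax(t - 1L, 1L)], 1)
  betaT <- schedule@beta[t]
  alphaT <- schedule@alpha[t]
  betaTilde <- pmax((1 - abPrev) / (1 - abT) * betaT, 1e-20)
  d <- dim(epsPred)
  ex <- function(v) array(v, d)  # per-sample scalars broadcast over latents
  v <- nnSigmoid(sigmaRaw)
  logSig <- v * log(ex(betaT)) + (1 - v) * log(ex(betaTilde))
  dmu <- ex(betaT / (sqrt(alphaT) * sqrt(1 - abT))) * (eps - epsPred)
  kl <- 0.5 * (logSig - log(ex(betaTilde)) +
                 (ex(betaTilde) + dmu^2) * exp(-logSig) - 1)
  dLogSig <- 0.5 * (1 - (ex(betaTilde) + dmu^2) * exp(-logSig)) / length(kl)
  dRaw <- dLogSig * (log(ex(betaT)) - log(ex(betaTilde))) * v * (1 - v)
  list(loss = mean(kl), dRaw = dRaw)
}

#' Train the conditional latent diffusion model
#'
#' Encodes the dataset to latents (identity/pixel mode when `vae` is `NULL`),
#' standardizes them by dataset-level statistics, and runs the denoising
#' objective: at each step it samples timesteps uniformly in `[1, T]` and
#' standard-normal noise, drops class labels to the null label with the
#' configured probability (classifier-free guidance training), minimizes the
#' noise MSE with AdamW, and maintains an EMA copy of the weights.
#'
#' @param dataset a [LabeledImageSet-class].
#' @param ditCfg a [ditConfig()].
#' @param trainCfg a [trainConfig()].
#' @param schedule a [NoiseSchedule-class].
#' @param vae optional trained VAE model from [trainVAE()]; `NULL` runs
#'   pixel-space diffusion.
#' @param verbose print running loss every 200 steps.
#' @return A checkpoint list of class `DiffusionCheckpoint` with raw and EMA
#'   weights, configs, latent standardization constants and loss history.
#' @export
trainDiffusion <- function(dataset, ditCfg, trainCfg, schedule = noiseSchedule(),
                           vae = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  set.seed(trainCfg$seed)
  if (is.null(vae)) {
    imgs <- imageData(dataset)
    d <- dim(imgs)
    lat <- array(imgs, c(d, 1L))
  } else {
    lat <- vaeEncode(dataset, vae)$mean
  }
  latMean <- mean(lat)
  latSd <- stats::sd(as.vector(lat))
  lat <- (lat - latMean) / latSd
  d <- dim(lat)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  labels <- imageLabels(dataset)
  if (any(labels >= ditCfg$numClasses)) stop("dataset labels exceed numClasses")

  model <- initDiT(ditCfg, H, C, seed = trainCfg$seed)
  state <- nnAdamInit(model$params)
  emaParams <- model$params
  lossHist <- numeric(trainCfg$totalSteps)

  for (step in seq_len(trainCfg$totalSteps)) {
    idx <- sample.int(N, trainCfg$batchSize, replace = N < trainCfg$batchSize)
    zb <- lat[idx, , , , drop = FALSE]
    if (trainCfg$horizontalFlip) {
      flip <- stats::runif(length(idx)) < 0.5
      if (any(flip)) zb[flip, , , ] <- zb[flip, , W:1, , drop = FALSE]
    }
    cls <- labels[idx]
    drop <- stats::runif(length(idx)) < ditCfg$labelDropoutProb
    cls[drop] <- NA
    t <- sample.int(schedule@steps, length(idx), replace = TRUE)
    eps <- array(stats::rnorm(length(zb)), dim(zb))
    zt <- qSample(zb, t, eps, schedule)
    fw <- ditForward(zt, t, cls, model, wantCache = TRUE)
    loss <- lossSimple(fw$eps, eps)
    if (!is.finite(loss))
      stop("non-finite loss at step ", step, " (last finite: ",
           signif(lossHist[max(step - 1L, 1L)], 4), ")")
    dEps <- 2 * (fw$eps - eps) / length(eps)
    dSigma <- NULL
    if (trainCfg$trainSigma) {
      sv <- sigmaVlb(fw$sigma, fw$eps, eps, t, schedule)
      loss <- loss + trainCfg$sigmaWeight * sv$loss
      dSigma <- trainCfg$sigmaWeight * sv$dRaw
    }
    grads <- ditBackward(dEps, dSigma, fw$cache, model)
    upd <- nnAdamStep(model$params, grads, state, lr = trainCfg$learningRate,
                      weightDecay = trainCfg$weightDecay)
    model$params <- upd$params
    state <- upd$state
    emaParams <- emaUpdate(emaParams, model$params, trainCfg$emaDecay)
    lossHist[step] <- loss
    if (verbose && step %% 200L == 0L)
      message(sprintf("step %d  loss %.4f", step,
                      mean(lossHist[max(1L, step - 49L):step])))
  }
  structure(list(params = model$params, emaParams = emaParams,
                 ditConfig = ditCfg, meta = model$meta, schedule = schedule,
                 latentMean = latMean, latentSd = latSd,
                 vae = vae, trainConfig = trainCfg, lossHistory = lossHist),
            class = "DiffusionCheckpoint")
}

#' Sampler configuration
#'
#' @param steps number of DDIM inference steps `S` (default 250).
#' @param omega classifier-free guidance strength (default 0.8).
#' @param eta DDIM stochasticity (default 0, deterministic).
#' @param seed integer seed for the initial noise (and `eta > 0` draws).
#' @return A list of class `SamplerConfig`.
#' @export
samplerConfig <- function(steps = 250L, omega = 0.8, eta = 0, seed = 1L) {
  stopifnot(steps >= 1L, omega >= 0, eta >= 0, eta <= 1)
  structure(list(steps = as.integer(steps), omega = omega, eta = eta,
                 seed = as.integer(seed)), class = "SamplerConfig")
}

# strictly decreasing DDIM timestep subsequence over [1, T], always
# including the terminal step T, ending at the first timestep
ddimTimesteps <- function(steps, S) {
  ts <- unique(as.integer(round(seq(steps, 1, length.out = min(S, steps)))))
  sort(ts, decreasing = TRUE)
}

#' Generate images from a trained checkpoint
#'
#' Draws seeded standard-normal terminal latents, runs the DDIM subsequence
#' with classifier-free guidance (two denoiser evaluations per step:
#' requested label and null label) on the EMA weights, destandardizes, and
#' decodes to images.
#'
#' @param checkpoint a `DiffusionCheckpoint` from [trainDiffusion()].
#' @param classLabel integer class to condition on, or `"all"` to cycle
#'   through every class.
#' @param n number of images (per the requested condition).
#' @param config a [samplerConfig()].
#' @param useEma use EMA weights (falls back to raw weights with a warning
#'   if the checkpoint lacks them).
#' @return A [LabeledImageSet-class] whose labels are the requested
#'   conditions; the sampler configuration is attached as attribute
#'   `samplerConfig`.
#' @export
sampleImages <- function(checkpoint, classLabel, n, config = samplerConfig(),
                         useEma = TRUE) {
  ditCfg <- checkpoint$ditConfig
  if (identical(classLabel, "all")) {
    cls <- rep(seq_len(ditCfg$numClasses) - 1L, length.out = n)
  } else {
    stopifnot(classLabel >= 0, classLabel < ditCfg$numClasses)
    cls <- rep(as.integer(classLabel), n)
  }
  params <- if (useEma && !is.null(checkpoint$emaParams)) checkpoint$emaParams
            else {
              if (useEma) warning("checkpoint has no EMA weights; using raw weights")
              checkpoint$params
            }
  model <- list(params = params, config = ditCfg, meta = checkpoint$meta)
  schedule <- checkpoint$schedule
  H <- checkpoint$meta$inputSize
  C <- checkpoint$meta$inputChannels
  set.seed(config$seed)
  z <- array(stats::rnorm(n * H * H * C), c(n, H, H, C))
  ts <- ddimTimesteps(schedule@steps, config$steps)
  for (i in seq_along(ts)) {
    t <- ts[i]
    tPrev <- if (i < length(ts)) ts[i + 1L] else 0L
    tv <- rep(t, n)
    epsC <- ditForward(z, tv, cls, model)$eps
    epsU <- ditForward(z, tv, rep(NA_integer_, n), model)$eps
    epsT <- cfgCombine(epsC, epsU, config$omega)
    z <- ddimStep(z, epsT, t, tPrev, schedule, eta = config$eta)
  }
  z <- z * checkpoint$latentSd + checkpoint$latentMean
  if (is.null(checkpoint$vae)) {
    imgs <- pmin(pmax(array(z, dim(z)[1:3]), 0), 1)
  } else {
    imgs <- vaeDecode(z, checkpoint$vae)
  }
  out <- LabeledImageSet(imgs, cls,
                         sprintf("synth-c%d-%05d", cls, seq_len(n)))
  attr(out, "samplerConfig") <- config
  out
}
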