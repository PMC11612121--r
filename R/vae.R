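#' Configuration for the latent variational autoencoder
#'
#' A small trainable VAE compresses images by an integer factor `f` into
#' `C`-channel latents. The encoder and decoder act on non-overlapping
#' `f x f` patches (strided convolutions with kernel = stride = `f`) with a
#' nonlinear hidden layer, so shapes follow `H/f x W/f x C` exactly.
#' `downsampleFactor = 1` selects a deterministic identity/bypass mode for
#' pixel-space diffusion.
#'
#' @param downsampleFactor `f`, one of 1, 2, 4, 8.
#' @param latentChannels latent channels `C` (default 4).
#' @param baseWidth hidden width of the per-patch encoder/decoder.
#' @param klWeight KL regularization weight `beta` (default 1e-3).
#' @param epochs,learningRate,batchSize training hyperparameters.
#' @param seed integer seed.
#' @return A list of class `VAEConfig`.
#' @export
vaeConfig <- function(downsampleFactor = 2L, latentChannels = 4L,
                      baseWidth = 32L, klWeight = 1e-3, epochs = 20L,
                      learningRate = 1e-3, batchSize = 32L, seed = 1L) {
  stopifnot(downsampleFactor %in% c(1L, 2L, 4L, 8L), latentChannels >= 1L,
            klWeight >= 0)
  structure(list(downsampleFactor = as.integer(downsampleFactor),
                 latentChannels = as.integer(latentChannels),
                 baseWidth = as.integer(baseWidth), klWeight = klWeight,
                 epochs = as.integer(epochs), learningRate = learningRate,
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "VAEConfig")
}

initVAE <- function(config, seed = config$seed) {
  set.seed(seed)
  f <- config$downsampleFactor
  if (f == 1L) return(list(params = NULL, config = config, identity = TRUE))
  pd <- f * f
  W <- config$baseWidth
  C <- config$latentChannels
  he <- function(fanIn) sqrt(2 / fanIn)
  params <- list()
  e1 <- nnLinearInit(pd, W, sd = he(pd))
  params[["enc.W1"]] <- e1$W; params[["enc.b1"]] <- e1$b
  mu <- nnLinearInit(W, C, sd = he(W))
  params[["enc.mu.W"]] <- mu$W; params[["enc.mu.b"]] <- mu$b
  lv <- nnLinearInit(W, C, sd = he(W))
  params[["enc.lv.W"]] <- lv$W
  params[["enc.lv.b"]] <- rep(-2, C)  # start with small posterior variance
  d1 <- nnLinearInit(C, W, sd = he(C))
  params[["dec.W1"]] <- d1$W; params[["dec.b1"]] <- d1$b
  d2 <- nnLinearInit(W, pd, sd = he(W))
  params[["dec.W2"]] <- d2$W; params[["dec.b2"]] <- d2$b
  list(params = params, config = config, identity = FALSE)
}

asImageArray <- function(images) {
  if (is(images, "LabeledImageSet")) images <- imageData(images)
  if (length(dim(images)) == 2L) dim(images) <- c(1L, dim(images))
  images
}

#' Encode images to latent posterior parameters
#'
#' Returns the posterior mean and log-variance latents of shape
#' `N x H/f x W/f x C`. In identity mode (`f = 1`) the mean equals the input
#' pixels exactly and the log-variance is `-Inf` (a deterministic,
#' zero-variance posterior surrogate).
#'
#' @param images a [LabeledImageSet-class] or `N x H x W` array.
#' @param vae a VAE model from [trainVAE()] (or `initVAE`).
#' @return A list with arrays `mean` and `logvar`.
#' @export
vaeEncode <- function(images, vae) {
  x <- asImageArray(images)
  d <- dim(x)
  f <- vae$config$downsampleFactor
  if (d[2L] %% f != 0L || d[3L] %% f != 0L)
    stop("image size not divisible by the downsampling factor")
  if (vae$identity) {
    m <- array(x, c(d, 1L))
    return(list(mean = m, logvar = array(-Inf, dim(m))))
  }
  p <- vae$params
  tok <- imPatchify(array(x, c(d, 1L)), f)
  h <- nnGeluFwd(nnLinearFwd(tok, p$enc.W1, p$enc.b1))
  mu <- nnLinearFwd(h, p$enc.mu.W, p$enc.mu.b)
  lv <- nnLinearFwd(h, p$enc.lv.W, p$enc.lv.b)
  C <- vae$config$latentChannels
  list(mean = imUnpatchify(mu, 1L, C, d[1L]),
       logvar = imUnpatchify(lv, 1L, C, d[1L]))
}

#' Reparameterization draw
#'
#' `sample = mean + exp(logvar / 2) * eps`, `eps ~ N(0, I)`; a `-Inf`
#' log-variance yields the mean exactly.
#'
#' @param mean,logvar arrays of identical shape.
#' @param seed optional integer seed.
#' @return Array of the same shape.
#' @export
vaeReparameterize <- function(mean, logvar, seed = NULL) {
  if (!identical(dim(mean), dim(logvar)))
    stop("mean and logvar shapes differ")
  if (!is.null(seed)) set.seed(seed)
  sd <- exp(logvar / 2)
  eps <- array(stats::rnorm(length(mean)), dim(mean))
  out <- mean + ifelse(is.finite(sd), sd, 0) * eps
  array(out, dim(mean))
}

#' Decode latents to images
#'
#' Output pixels are bounded to `[0, 1]` by a sigmoid activation; identity
#' mode inverts [vaeEncode()] exactly (up to clipping into `[0, 1]`).
#'
#' @param z latent array `N x H/f x W/f x C`.
#' @param vae a VAE model.
#' @return `N x H x W` image array in `[0, 1]`.
#' @export
vaeDecode <- function(z, vae) {
  d <- dim(z)
  if (vae$identity) {
    return(pmin(pmax(array(z, d[1:3]), 0), 1))
  }
  if (d[4L] != vae$config$latentChannels) stop("latent channels mismatch")
  p <- vae$params
  f <- vae$config$downsampleFactor
  tok <- imPatchify(z, 1L)
  h <- nnGeluFwd(nnLinearFwd(tok, p$dec.W1, p$dec.b1))
  out <- nnSigmoid(nnLinearFwd(h, p$dec.W2, p$dec.b2))
  arr <- imUnpatchify(out, f, 1L, d[1L])
  array(arr, c(d[1L], d[2L] * f, d[3L] * f))
}

#' Train the VAE
#'
#' Minimizes mean reconstruction MSE plus `beta` times the KL divergence of
#' the per-element posterior `N(mean, exp(logvar))` from the standard
#' normal, with Adam. `beta = 0` reduces the objective to pure
#' reconstruction. Identity mode returns the bypass model untrained.
#'
#' @param dataset a [LabeledImageSet-class].
#' @param config a [vaeConfig()].
#' @param verbose print per-epoch loss.
#' @return A VAE model list with `params`, `config`, `identity`,
#'   `lossHistory` (per-epoch mean objective) and `latentStats`
#'   (dataset-level mean/sd of the latent means, the scale factor applied
#'   before diffusion).
#' @export
trainVAE <- function(dataset, config = vaeConfig(), verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  vae <- initVAE(config)
  if (vae$identity) {
    vae$lossHistory <- numeric(0)
    vae$latentStats <- c(mean = 0.5, sd = 0.5)
    return(vae)
  }
  set.seed(config$seed)
  x <- asImageArray(dataset)
  N <- dim(x)[1L]
  f <- config$downsampleFactor
  state <- nnAdamInit(vae$params)
  lossHist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epLoss <- 0
    for (bidx in batches) {
      p <- vae$params
      xb <- x[bidx, , , drop = FALSE]
      B <- length(bidx)
      tok <- imPatchify(array(xb, c(dim(xb), 1L)), f)
      hPre <- nnLinearFwd(tok, p$enc.W1, p$enc.b1)
      hc <- nnGeluFwdC(hPre)
      h <- hc$out
      mu <- nnLinearFwd(h, p$enc.mu.W, p$enc.mu.b)
      lv <- nnLinearFwd(h, p$enc.lv.W, p$enc.lv.b)
      eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
      zs <- mu + exp(lv / 2) * eps
      dhPre2 <- nnLinearFwd(zs, p$dec.W1, p$dec.b1)
      dhc <- nnGeluFwdC(dhPre2)
      dh <- dhc$out
      outPre <- nnLinearFwd(dh, p$dec.W2, p$dec.b2)
      out <- nnSigmoid(outPre)

      nPix <- length(tok)
      nLat <- length(mu)
      recon <- sum((out - tok)^2) / nPix
      kl <- sum(0.5 * (mu^2 + exp(lv) - lv - 1)) / nLat
      loss <- recon + config$klWeight * kl
      epLoss <- epLoss + loss * B

      g <- list()
      dOut <- 2 * (out - tok) / nPix
      dOutPre <- dOut * out * (1 - out)
      l4 <- nnLinearBwd(dOutPre, dh, p$dec.W2)
      g[["dec.W2"]] <- l4$dW; g[["dec.b2"]] <- l4$db
      dDhPre <- nnGeluBwdC(l4$dx, dhPre2, dhc$t)
      l3 <- nnLinearBwd(dDhPre, zs, p$dec.W1)
      g[["dec.W1"]] <- l3$dW; g[["dec.b1"]] <- l3$db
      dzs <- l3$dx
      dMu <- dzs + config$klWeight * mu / nLat
      dLv <- dzs * eps * exp(lv / 2) / 2 +
        config$klWeight * 0.5 * (exp(lv) - 1) / nLat
      lmu <- nnLinearBwd(dMu, h, p$enc.mu.W)
      g[["enc.mu.W"]] <- lmu$dW; g[["enc.mu.b"]] <- lmu$db
      llv <- nnLinearBwd(dLv, h, p$enc.lv.W)
      g[["enc.lv.W"]] <- llv$dW; g[["enc.lv.b"]] <- llv$db
      dhEnc <- nnGeluBwdC(lmu$dx + llv$dx, hPre, hc$t)
      l1 <- nnLinearBwd(dhEnc, tok, p$enc.W1)
      g[["enc.W1"]] <- l1$dW; g[["enc.b1"]] <- l1$db

      upd <- nnAdamStep(vae$params, g, state, lr = config$learningRate)
      vae$params <- upd$params
      state <- upd$state
    }
    lossHist[ep] <- epLoss / N
    if (verbose) message(sprintf("epoch %d  loss %.5f", ep, lossHist[ep]))
  }
  vae$lossHistory <- lossHist
  enc <- vaeEncode(x, vae)
  vae$latentStats <- c(mean = mean(enc$mean), sd = stats::sd(as.vector(enc$mean)))
  vae
}

#' Mean reconstruction error of a VAE on a dataset
#'
#' @param dataset a [LabeledImageSet-class] or image array.
#' @param vae a VAE model.
#' @return Mean squared reconstruction error over all pixels (posterior
#'   means, no sampling).
#' @export
vaeReconstructionError <- function(dataset, vae) {
  x <- asImageArray(dataset)
  enc <- vaeEncode(x, vae)
  rec <- vaeDecode(enc$mean, vae)
  mean((rec - x)^2)
}
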