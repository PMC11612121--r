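#' Configuration for the diffusion-transformer denoiser
#'
#' The denoiser patchifies the (noisy) latent into tokens, adds fixed 2-D
#' sinusoidal positional embeddings, and runs `depth` adaLN-Zero transformer
#' blocks: layer-norm scale/shift and residual gates are regressed from a
#' conditioning vector (timestep embedding + class-label embedding) with
#' zero-initialized gate projections, so every residual branch — and the
#' zero-initialized final linear head — contributes exactly zero at
#' initialization. The head emits `2C` channels per latent channel pair:
#' predicted noise and covariance channels.
#'
#' @param patchSize patch side `p` (default 2).
#' @param hiddenDim token embedding width (divisible by `numHeads` and 4).
#' @param depth number of adaLN-Zero blocks.
#' @param numHeads attention heads.
#' @param numClasses number of conditioning classes; the null
#'   (unconditional) label used for classifier-free guidance gets its own
#'   learned embedding row.
#' @param labelDropoutProb probability of replacing the class label with the
#'   null label during training (classifier-free guidance training).
#' @param mlpRatio width multiplier of the per-token MLP.
#' @return A list of class `DiTConfig`.
#' @export
ditConfig <- function(patchSize = 2L, hiddenDim = 128L, depth = 4L,
                      numHeads = 4L, numClasses = 5L,
                      labelDropoutProb = 0.1, mlpRatio = 4L) {
  stopifnot(hiddenDim %% numHeads == 0L, hiddenDim %% 4L == 0L,
            labelDropoutProb >= 0, labelDropoutProb <= 1, depth >= 1L)
  structure(list(patchSize = as.integer(patchSize),
                 hiddenDim = as.integer(hiddenDim),
                 depth = as.integer(depth),
                 numHeads = as.integer(numHeads),
                 numClasses = as.integer(numClasses),
                 labelDropoutProb = labelDropoutProb,
                 mlpRatio = as.integer(mlpRatio)),
            class = "DiTConfig")
}

#' Initialize DiT parameters
#'
#' Truncated-normal initialization for projections (the ViT convention),
#' zeros for all adaLN modulation projections and the final linear head.
#'
#' @param config a [ditConfig()].
#' @param inputSize latent spatial side (divisible by `patchSize`).
#' @param inputChannels latent channels `C`.
#' @param seed integer seed for the initialization draw.
#' @return A list with `params` (flat named list), `meta` (token geometry,
#'   positional embeddings), and `config`.
#' @export
initDiT <- function(config, inputSize, inputChannels, seed = 1L) {
  set.seed(seed)
  p <- config$patchSize
  D <- config$hiddenDim
  if (inputSize %% p != 0L) stop("inputSize must be divisible by patchSize")
  g <- inputSize %/% p
  pd <- p * p * inputChannels
  params <- list()
  lin <- function(i, o, zero = FALSE) nnLinearInit(i, o, zero = zero)
  pp <- lin(pd, D); params[["patch.W"]] <- pp$W; params[["patch.b"]] <- pp$b
  tm1 <- lin(D, D); tm2 <- lin(D, D)
  params[["tmlp.W1"]] <- tm1$W; params[["tmlp.b1"]] <- tm1$b
  params[["tmlp.W2"]] <- tm2$W; params[["tmlp.b2"]] <- tm2$b
  params[["label.E"]] <- matrix(nnTruncNormal((config$numClasses + 1L) * D), config$numClasses + 1L, D)
  for (i in seq_len(config$depth)) {
    pre <- sprintf("blk%d.", i)
    qkv <- lin(D, 3L * D); prj <- lin(D, D)
    m1 <- lin(D, config$mlpRatio * D); m2 <- lin(config$mlpRatio * D, D)
    ada <- lin(D, 6L * D, zero = TRUE)
    params[[paste0(pre, "qkv.W")]] <- qkv$W; params[[paste0(pre, "qkv.b")]] <- qkv$b
    params[[paste0(pre, "proj.W")]] <- prj$W; params[[paste0(pre, "proj.b")]] <- prj$b
    params[[paste0(pre, "mlp.W1")]] <- m1$W; params[[paste0(pre, "mlp.b1")]] <- m1$b
    params[[paste0(pre, "mlp.W2")]] <- m2$W; params[[paste0(pre, "mlp.b2")]] <- m2$b
    params[[paste0(pre, "ada.W")]] <- ada$W; params[[paste0(pre, "ada.b")]] <- ada$b
  }
  fada <- lin(D, 2L * D, zero = TRUE)
  head <- lin(D, p * p * 2L * inputChannels, zero = TRUE)
  params[["final.ada.W"]] <- fada$W; params[["final.ada.b"]] <- fada$b
  params[["final.W"]] <- head$W; params[["final.b"]] <- head$b
  list(params = params, config = config,
       meta = list(inputSize = as.integer(inputSize),
                   inputChannels = as.integer(inputChannels),
                   grid = g, tokens = g * g,
                   pos = posEmbed2D(g, D)))
}

# sinusoidal frequency embedding of (possibly fractional) timesteps, B x D
ditFreqEmbed <- function(t, D) {
  half <- D %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / half)
  ang <- outer(as.numeric(t), freqs)
  cbind(cos(ang), sin(ang))
}

#' Conditioning embedding for timestep and class label
#'
#' Sinusoidal timestep embedding through a two-layer perceptron, summed with
#' a learned label-table row; `NA` labels select the dedicated null row used
#' for classifier-free guidance.
#'
#' @param t integer timesteps (vector), `1 <= t <= T`.
#' @param cls integer class labels in `[0, numClasses)` or `NA` for the null
#'   label.
#' @param model a model list from [initDiT()].
#' @return A list with the `B x hiddenDim` conditioning matrix `cond` and a
#'   cache for backpropagation.
#' @export
conditionEmbed <- function(t, cls, model) {
  params <- model$params; config <- model$config
  if (any(t < 1L)) stop("timestep out of range")
  bad <- !is.na(cls) & (cls < 0L | cls >= config$numClasses)
  if (any(bad)) stop("class label out of range")
  clsIdx <- ifelse(is.na(cls), config$numClasses + 1L, cls + 1L)
  fe <- ditFreqEmbed(t, config$hiddenDim)
  h1pre <- nnLinearFwd(fe, params$tmlp.W1, params$tmlp.b1)
  h1 <- nnSiluFwd(h1pre)
  tEmb <- nnLinearFwd(h1, params$tmlp.W2, params$tmlp.b2)
  lEmb <- params$label.E[clsIdx, , drop = FALSE]
  list(cond = tEmb + lEmb,
       cache = list(fe = fe, h1pre = h1pre, h1 = h1, clsIdx = clsIdx))
}

# backprop through the conditioning pathway; returns parameter gradients
conditionEmbedBwd <- function(dCond, cache, params) {
  g <- list()
  g[["label.E"]] <- matrix(0, nrow(params$label.E), ncol(params$label.E))
  agg <- rowsum(dCond, cache$clsIdx)
  g[["label.E"]][as.integer(rownames(agg)), ] <- agg
  l2 <- nnLinearBwd(dCond, cache$h1, params$tmlp.W2)
  g[["tmlp.W2"]] <- l2$dW; g[["tmlp.b2"]] <- l2$db
  dh1pre <- nnSiluBwd(l2$dx, cache$h1pre)
  l1 <- nnLinearBwd(dh1pre, cache$fe, params$tmlp.W1)
  g[["tmlp.W1"]] <- l1$dW; g[["tmlp.b1"]] <- l1$db
  g
}

# multi-head self-attention over sample-major token blocks.
# X: (B*Tn) x D already projected to qkv; returns output and cache.
ditAttentionFwd <- function(qkv, B, Tn, numHeads) {
  D <- ncol(qkv) %/% 3L
  dh <- D %/% numHeads
  out <- matrix(0, nrow(qkv), D)
  probs <- vector("list", B * numHeads)
  scale <- 1 / sqrt(dh)
  for (s in seq_len(B)) {
    rows <- ((s - 1L) * Tn + 1L):(s * Tn)
    for (h in seq_len(numHeads)) {
      cq <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- qkv[rows, cq, drop = FALSE]
      K <- qkv[rows, D + cq, drop = FALSE]
      V <- qkv[rows, 2L * D + cq, drop = FALSE]
      P <- nnSoftmaxRows(tcrossprod(Q, K) * scale)
      out[rows, cq] <- P %*% V
      probs[[(s - 1L) * numHeads + h]] <- P
    }
  }
  list(out = out, probs = probs)
}

ditAttentionBwd <- function(dOut, qkv, cache, B, Tn, numHeads) {
  D <- ncol(qkv) %/% 3L
  dh <- D %/% numHeads
  dqkv <- matrix(0, nrow(qkv), 3L * D)
  scale <- 1 / sqrt(dh)
  for (s in seq_len(B)) {
    rows <- ((s - 1L) * Tn + 1L):(s * Tn)
    for (h in seq_len(numHeads)) {
      cq <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- qkv[rows, cq, drop = FALSE]
      K <- qkv[rows, D + cq, drop = FALSE]
      V <- qkv[rows, 2L * D + cq, drop = FALSE]
      P <- cache$probs[[(s - 1L) * numHeads + h]]
      dO <- dOut[rows, cq, drop = FALSE]
      dP <- tcrossprod(dO, V)
      dV <- crossprod(P, dO)
      dS <- nnSoftmaxRowsBwd(dP, P) * scale
      dqkv[rows, cq] <- dS %*% K
      dqkv[rows, D + cq] <- crossprod(dS, Q)
      dqkv[rows, 2L * D + cq] <- dV
    }
  }
  dqkv
}

#' Denoiser forward pass
#'
#' Runs the full adaLN-Zero transformer: patchify + positional embedding,
#' `depth` conditioned blocks, final adaptive layer norm and zero-initialized
#' linear head, and unpatchify into predicted-noise and covariance channels.
#' At initialization the output is identically zero for any input.
#'
#' @param z noisy latent batch, `B x H x W x C` array (or `H x W x C` for a
#'   single sample).
#' @param t integer timesteps, length `B`.
#' @param cls integer class labels (`NA` = null/unconditional), length `B`.
#' @param model model list from [initDiT()] (pass `modifyList(model,
#'   list(params = emaParams))` to evaluate EMA weights).
#' @param wantCache keep intermediate activations for [ditBackward()].
#' @return A list with `eps` and `sigma` arrays shaped like `z`, plus
#'   `cache` when requested.
#' @export
ditForward <- function(z, t, cls, model, wantCache = FALSE) {
  if (length(dim(z)) == 3L) dim(z) <- c(1L, dim(z))
  params <- model$params; config <- model$config; meta <- model$meta
  d <- dim(z)
  B <- d[1L]; C <- d[4L]
  if (d[2L] != meta$inputSize || C != meta$inputChannels)
    stop("latent shape does not match the model configuration")
  Tn <- meta$tokens
  p <- config$patchSize
  grp <- rep(seq_len(B), each = Tn)
  tokRep <- rep(seq_len(Tn), times = B)

  tok0 <- imPatchify(z, p)
  X <- nnLinearFwd(tok0, params$patch.W, params$patch.b) + meta$pos[tokRep, , drop = FALSE]
  ce <- conditionEmbed(t, cls, model)
  cvec <- ce$cond
  cact <- nnSiluFwd(cvec)

  cache <- list(tok0 = tok0, ce = ce, cvec = cvec, cact = cact, grp = grp,
                B = B, Tn = Tn, C = C, blocks = vector("list", config$depth))
  for (i in seq_len(config$depth)) {
    pre <- sprintf("blk%d.", i)
    m <- nnLinearFwd(cact, params[[paste0(pre, "ada.W")]], params[[paste0(pre, "ada.b")]])
    D <- config$hiddenDim
    mE <- m[grp, , drop = FALSE]
    shift1 <- mE[, 1:D]; scale1 <- mE[, D + 1:D]; gate1 <- mE[, 2 * D + 1:D]
    shift2 <- mE[, 3 * D + 1:D]; scale2 <- mE[, 4 * D + 1:D]; gate2 <- mE[, 5 * D + 1:D]

    ln1 <- nnLayerNormFwd(X)
    xm <- ln1$out * (1 + scale1) + shift1
    qkv <- nnLinearFwd(xm, params[[paste0(pre, "qkv.W")]], params[[paste0(pre, "qkv.b")]])
    att <- ditAttentionFwd(qkv, B, Tn, config$numHeads)
    ao <- nnLinearFwd(att$out, params[[paste0(pre, "proj.W")]], params[[paste0(pre, "proj.b")]])
    X2 <- X + gate1 * ao

    ln2 <- nnLayerNormFwd(X2)
    xm2 <- ln2$out * (1 + scale2) + shift2
    mhPre <- nnLinearFwd(xm2, params[[paste0(pre, "mlp.W1")]], params[[paste0(pre, "mlp.b1")]])
    mhC <- nnGeluFwdC(mhPre)
    mh <- mhC$out
    mo <- nnLinearFwd(mh, params[[paste0(pre, "mlp.W2")]], params[[paste0(pre, "mlp.b2")]])
    X3 <- X2 + gate2 * mo

    if (wantCache)
      cache$blocks[[i]] <- list(X = X, ln1 = ln1, xm = xm, qkv = qkv, att = att,
                                ao = ao, X2 = X2, ln2 = ln2, xm2 = xm2,
                                mhPre = mhPre, mhT = mhC$t, mh = mh, mo = mo,
                                mE = mE)
    X <- X3
  }
  mF <- nnLinearFwd(cact, params$final.ada.W, params$final.ada.b)
  D <- config$hiddenDim
  mFE <- mF[grp, , drop = FALSE]
  shiftF <- mFE[, 1:D]; scaleF <- mFE[, D + 1:D]
  lnF <- nnLayerNormFwd(X)
  xf <- lnF$out * (1 + scaleF) + shiftF
  outTok <- nnLinearFwd(xf, params$final.W, params$final.b)
  outArr <- imUnpatchify(outTok, p, 2L * C, B)
  eps <- outArr[, , , seq_len(C), drop = FALSE]
  sigma <- outArr[, , , C + seq_len(C), drop = FALSE]
  if (wantCache) {
    cache$Xfinal <- X; cache$lnF <- lnF; cache$xf <- xf; cache$mFE <- mFE
  }
  list(eps = eps, sigma = sigma, cache = if (wantCache) cache else NULL)
}

#' Denoiser backward pass
#'
#' Backpropagates gradients of a scalar loss with respect to the predicted
#' noise (and optionally covariance) channels through the whole transformer,
#' including the conditioning pathway (timestep MLP and label table).
#'
#' @param dEps gradient w.r.t. `eps`, same shape as the latent batch.
#' @param dSigma gradient w.r.t. `sigma` (or `NULL` for zero).
#' @param cache the cache returned by `ditForward(..., wantCache = TRUE)`.
#' @param model the model list used in the forward pass.
#' @return Flat named list of parameter gradients.
#' @export
ditBackward <- function(dEps, dSigma, cache, model) {
  params <- model$params; config <- model$config
  B <- cache$B; Tn <- cache$Tn; C <- cache$C
  p <- config$patchSize
  D <- config$hiddenDim
  grp <- cache$grp
  if (length(dim(dEps)) == 3L) dim(dEps) <- c(1L, dim(dEps))
  if (is.null(dSigma)) dSigma <- array(0, dim(dEps))
  if (length(dim(dSigma)) == 3L) dim(dSigma) <- c(1L, dim(dSigma))
  dOutArr <- array(0, c(B, dim(dEps)[2L], dim(dEps)[3L], 2L * C))
  dOutArr[, , , seq_len(C)] <- dEps
  dOutArr[, , , C + seq_len(C)] <- dSigma
  dOutTok <- imPatchify(dOutArr, p)

  g <- list()
  lb <- nnLinearBwd(dOutTok, cache$xf, params$final.W)
  g[["final.W"]] <- lb$dW; g[["final.b"]] <- lb$db
  dxf <- lb$dx
  dlnF <- dxf * (1 + cache$mFE[, D + 1:D])
  dmFE <- matrix(0, nrow(dxf), 2L * D)
  dmFE[, 1:D] <- dxf
  dmFE[, D + 1:D] <- dxf * cache$lnF$out
  dmF <- rowsum(dmFE, grp)
  g[["final.ada.W"]] <- crossprod(cache$cact, dmF)
  g[["final.ada.b"]] <- colSums(dmF)
  dcact <- tcrossprod(dmF, params$final.ada.W)
  dX <- nnLayerNormBwd(dlnF, cache$lnF)

  for (i in rev(seq_len(config$depth))) {
    pre <- sprintf("blk%d.", i)
    bc <- cache$blocks[[i]]
    mE <- bc$mE
    shift1 <- mE[, 1:D]; scale1 <- mE[, D + 1:D]; gate1 <- mE[, 2 * D + 1:D]
    scale2 <- mE[, 4 * D + 1:D]; gate2 <- mE[, 5 * D + 1:D]

    # X3 = X2 + gate2 * mo
    dX2 <- dX
    dmo <- dX * gate2
    dgate2 <- dX * bc$mo
    l2 <- nnLinearBwd(dmo, bc$mh, params[[paste0(pre, "mlp.W2")]])
    g[[paste0(pre, "mlp.W2")]] <- l2$dW; g[[paste0(pre, "mlp.b2")]] <- l2$db
    dmhPre <- nnGeluBwdC(l2$dx, bc$mhPre, bc$mhT)
    l1 <- nnLinearBwd(dmhPre, bc$xm2, params[[paste0(pre, "mlp.W1")]])
    g[[paste0(pre, "mlp.W1")]] <- l1$dW; g[[paste0(pre, "mlp.b1")]] <- l1$db
    dxm2 <- l1$dx
    dln2 <- dxm2 * (1 + scale2)
    dscale2 <- dxm2 * bc$ln2$out
    dshift2 <- dxm2
    dX2 <- dX2 + nnLayerNormBwd(dln2, bc$ln2)

    # X2 = X + gate1 * ao
    dXlocal <- dX2
    dao <- dX2 * gate1
    dgate1 <- dX2 * bc$ao
    lp <- nnLinearBwd(dao, bc$att$out, params[[paste0(pre, "proj.W")]])
    g[[paste0(pre, "proj.W")]] <- lp$dW; g[[paste0(pre, "proj.b")]] <- lp$db
    dattOut <- lp$dx
    dqkv <- ditAttentionBwd(dattOut, bc$qkv, bc$att, B, Tn, config$numHeads)
    lq <- nnLinearBwd(dqkv, bc$xm, params[[paste0(pre, "qkv.W")]])
    g[[paste0(pre, "qkv.W")]] <- lq$dW; g[[paste0(pre, "qkv.b")]] <- lq$db
    dxm <- lq$dx
    dln1 <- dxm * (1 + scale1)
    dscale1 <- dxm * bc$ln1$out
    dshift1 <- dxm
    dXlocal <- dXlocal + nnLayerNormBwd(dln1, bc$ln1)

    dmE <- matrix(0, nrow(dxm), 6L * D)
    dmE[, 1:D] <- dshift1
    dmE[, D + 1:D] <- dscale1
    dmE[, 2 * D + 1:D] <- dgate1
    dmE[, 3 * D + 1:D] <- dshift2
    dmE[, 4 * D + 1:D] <- dscale2
    dmE[, 5 * D + 1:D] <- dgate2
    dm <- rowsum(dmE, grp)
    g[[paste0(pre, "ada.W")]] <- crossprod(cache$cact, dm)
    g[[paste0(pre, "ada.b")]] <- colSums(dm)
    dcact <- dcact + tcrossprod(dm, params[[paste0(pre, "ada.W")]])
    dX <- dXlocal
  }

  # patch projection
  lpz <- nnLinearBwd(dX, cache$tok0, params$patch.W)
  g[["patch.W"]] <- lpz$dW; g[["patch.b"]] <- lpz$db

  # conditioning pathway
  dCond <- nnSiluBwd(dcact, cache$cvec)
  gc <- conditionEmbedBwd(dCond, cache$ce$cache, params)
  g <- c(g, gc)
  g
}

#' Number of trainable parameters of a DiT model
#' @param model a model list from [initDiT()].
#' @return Integer parameter count.
#' @export
ditParameterCount <- function(model) {
  sum(vapply(model$params, length, 0L))
}
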