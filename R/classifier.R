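#' Configuration for the residual bottleneck image classifier
#'
#' A small convolutional network in the spirit of deep residual classifiers
#' with bottleneck blocks, scaled to desk size: a 2x2-stride patch
#' convolution stem, then stages of (1x1-conv bottleneck residual block +
#' 2x2-stride patch-convolution downsampling), global average pooling, and a
#' linear softmax head. The pooled penultimate activation is the feature
#' vector reused by the generative metrics and the privacy audit.
#'
#' @param widths channel widths per stage (length = number of stages); the
#'   last width is the feature dimension.
#' @param stemPatch stride/kernel of the stem patch convolution (default 4,
#'   mirroring the stride-2 stem + pooling entry of deep residual nets).
#' @param epochs training epochs (default 50).
#' @param batchSize minibatch size (default 32).
#' @param learningRate AdamW learning rate (default 1e-4).
#' @param weightDecay decoupled weight decay (default 0).
#' @param seed integer seed.
#' @return A list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(widths = c(16L, 32L, 64L), stemPatch = 4L,
                             epochs = 50L, batchSize = 32L,
                             learningRate = 1e-4, weightDecay = 0,
                             seed = 1L) {
  stopifnot(epochs >= 1, batchSize >= 1, learningRate > 0,
            all(widths %% 2L == 0L), stemPatch %in% c(2L, 4L))
  structure(list(widths = as.integer(widths), stemPatch = as.integer(stemPatch),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, weightDecay = weightDecay,
                 seed = as.integer(seed)), class = "ClassifierConfig")
}

initClassifier <- function(config, inputSize, numClasses, seed = config$seed) {
  set.seed(seed)
  ws <- config$widths
  nStage <- length(ws)
  sp <- config$stemPatch
  if (inputSize %% (sp * 2L^(nStage - 1L)) != 0L)
    stop("inputSize must be divisible by stemPatch * 2^(stages - 1)")
  params <- list()
  he <- function(fanIn) sqrt(2 / fanIn)   # fan-in scaled init
  st <- nnLinearInit(sp * sp, ws[1L], sd = he(sp * sp))
  params[["stem.W"]] <- st$W; params[["stem.b"]] <- st$b
  for (i in seq_len(nStage)) {
    w <- ws[i]
    b1 <- nnLinearInit(w, w %/% 2L, sd = he(w))
    b2 <- nnLinearInit(w %/% 2L, w, sd = he(w %/% 2L))
    params[[sprintf("st%d.bn1.W", i)]] <- b1$W
    params[[sprintf("st%d.bn1.b", i)]] <- b1$b
    params[[sprintf("st%d.bn2.W", i)]] <- b2$W
    params[[sprintf("st%d.bn2.b", i)]] <- b2$b
    if (i < nStage) {
      ds <- nnLinearInit(4L * w, ws[i + 1L], sd = he(4L * w))
      params[[sprintf("st%d.ds.W", i)]] <- ds$W
      params[[sprintf("st%d.ds.b", i)]] <- ds$b
    }
  }
  hd <- nnLinearInit(ws[nStage], numClasses, sd = he(ws[nStage]))
  params[["head.W"]] <- hd$W; params[["head.b"]] <- hd$b
  list(params = params, config = config, inputSize = as.integer(inputSize),
       numClasses = as.integer(numClasses))
}

# forward through the CNN; returns logits, pooled features and (optionally)
# the per-layer cache for backprop
classifierForward <- function(params, config, x, wantCache = FALSE) {
  d <- dim(x)   # [B, H, W]
  B <- d[1L]
  ws <- config$widths
  nStage <- length(ws)
  cache <- list(B = B, stages = vector("list", nStage))
  a <- array(x, c(d, 1L))
  sp <- config$stemPatch
  tok <- imPatchify(a, sp)                      # (B*g^2) x sp^2
  hPre <- nnLinearFwd(tok, params$stem.W, params$stem.b)
  hC <- nnGeluFwdC(hPre)
  h <- hC$out
  g <- d[2L] %/% sp
  if (wantCache) { cache$tok0 <- tok; cache$stemPre <- hPre; cache$stemT <- hC$t }
  for (i in seq_len(nStage)) {
    w <- ws[i]
    b1Pre <- nnLinearFwd(h, params[[sprintf("st%d.bn1.W", i)]],
                         params[[sprintf("st%d.bn1.b", i)]])
    b1C <- nnGeluFwdC(b1Pre)
    b1 <- b1C$out
    b2 <- nnLinearFwd(b1, params[[sprintf("st%d.bn2.W", i)]],
                      params[[sprintf("st%d.bn2.b", i)]])
    hRes <- h + b2
    sc <- list(hIn = h, b1Pre = b1Pre, b1T = b1C$t, b1 = b1, g = g)
    h <- hRes
    if (i < nStage) {
      arr <- imUnpatchify(h, 1L, w, B)          # [B, g, g, w]
      tok2 <- imPatchify(arr, 2L)               # (B*(g/2)^2) x 4w
      dsPre <- nnLinearFwd(tok2, params[[sprintf("st%d.ds.W", i)]],
                           params[[sprintf("st%d.ds.b", i)]])
      sc$tok2 <- tok2; sc$dsPre <- dsPre
      dsC <- nnGeluFwdC(dsPre)
      sc$dsT <- dsC$t
      h <- dsC$out
      g <- g %/% 2L
    }
    if (wantCache) cache$stages[[i]] <- sc
  }
  # global average pool over the g*g spatial rows of each sample
  grp <- rep(seq_len(B), each = g * g)
  feats <- rowsum(h, grp) / (g * g)
  logits <- nnLinearFwd(feats, params$head.W, params$head.b)
  if (wantCache) { cache$hLast <- h; cache$gLast <- g; cache$feats <- feats }
  list(logits = logits, features = feats, cache = if (wantCache) cache else NULL)
}

classifierBackward <- function(dLogits, cache, params, config) {
  ws <- config$widths
  nStage <- length(ws)
  B <- cache$B
  g <- list()
  lh <- nnLinearBwd(dLogits, cache$feats, params$head.W)
  g[["head.W"]] <- lh$dW; g[["head.b"]] <- lh$db
  gL <- cache$gLast
  dh <- lh$dx[rep(seq_len(B), each = gL * gL), , drop = FALSE] / (gL * gL)
  for (i in rev(seq_len(nStage))) {
    sc <- cache$stages[[i]]
    w <- ws[i]
    if (i < nStage) {
      dDsPre <- nnGeluBwdC(dh, sc$dsPre, sc$dsT)
      ld <- nnLinearBwd(dDsPre, sc$tok2, params[[sprintf("st%d.ds.W", i)]])
      g[[sprintf("st%d.ds.W", i)]] <- ld$dW
      g[[sprintf("st%d.ds.b", i)]] <- ld$db
      dArr <- imUnpatchify(ld$dx, 2L, w, B)     # [B, g, g, w]
      dh <- imPatchify(dArr, 1L)                # rows per pixel
    }
    # residual: h_out = h_in + W2 gelu(W1 h_in)
    l2 <- nnLinearBwd(dh, sc$b1, params[[sprintf("st%d.bn2.W", i)]])
    g[[sprintf("st%d.bn2.W", i)]] <- l2$dW
    g[[sprintf("st%d.bn2.b", i)]] <- l2$db
    dB1Pre <- nnGeluBwdC(l2$dx, sc$b1Pre, sc$b1T)
    l1 <- nnLinearBwd(dB1Pre, sc$hIn, params[[sprintf("st%d.bn1.W", i)]])
    g[[sprintf("st%d.bn1.W", i)]] <- l1$dW
    g[[sprintf("st%d.bn1.b", i)]] <- l1$db
    dh <- dh + l1$dx
  }
  dStemPre <- nnGeluBwdC(dh, cache$stemPre, cache$stemT)
  ls <- nnLinearBwd(dStemPre, cache$tok0, params$stem.W)
  g[["stem.W"]] <- ls$dW; g[["stem.b"]] <- ls$db
  g
}

#' Train the image classifier
#'
#' Softmax cross-entropy with AdamW on the configured schedule.
#'
#' @param dataset a [LabeledImageSet-class]; labels must be `0 .. K-1`.
#' @param config a [classifierConfig()].
#' @param numClasses number of classes `K` (default: max label + 1).
#' @param verbose print per-epoch training loss.
#' @return A classifier model list (class `PhantomClassifier`) with
#'   `params`, `config`, `inputSize`, `numClasses`, `lossHistory`.
#' @export
trainClassifier <- function(dataset, config = classifierConfig(),
                            numClasses = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  labels <- imageLabels(dataset)
  if (is.null(numClasses)) numClasses <- max(labels) + 1L
  if (length(unique(labels)) < 2L) stop("need at least two classes present")
  x <- imageData(dataset)
  N <- dim(x)[1L]
  model <- initClassifier(config, dim(x)[2L], numClasses)
  set.seed(config$seed)
  state <- nnAdamInit(model$params)
  lossHist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epLoss <- 0
    for (bidx in batches) {
      xb <- x[bidx, , , drop = FALSE]
      yb <- labels[bidx] + 1L
      fw <- classifierForward(model$params, config, xb, wantCache = TRUE)
      p <- nnSoftmaxRows(fw$logits)
      loss <- -mean(log(pmax(p[cbind(seq_along(yb), yb)], 1e-12)))
      epLoss <- epLoss + loss * length(bidx)
      dLogits <- p
      dLogits[cbind(seq_along(yb), yb)] <- dLogits[cbind(seq_along(yb), yb)] - 1
      dLogits <- dLogits / length(bidx)
      grads <- classifierBackward(dLogits, fw$cache, model$params, config)
      upd <- nnAdamStep(model$params, grads, state, lr = config$learningRate,
                        weightDecay = config$weightDecay)
      model$params <- upd$params
      state <- upd$state
    }
    lossHist[ep] <- epLoss / N
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, lossHist[ep]))
  }
  model$lossHistory <- lossHist
  class(model) <- "PhantomClassifier"
  model
}

#' Classifier predictions and features
#'
#' @param model a trained classifier from [trainClassifier()].
#' @param images a [LabeledImageSet-class] or `N x H x W` array (resized by
#'   mean pooling if an integer multiple of the training size).
#' @return A list with `probs` (`N x K` softmax rows) and `features`
#'   (`N x F` pooled penultimate activations).
#' @export
predictClassifier <- function(model, images) {
  x <- asImageArray(images)
  if (dim(x)[2L] != model$inputSize) {
    if (dim(x)[2L] %% model$inputSize == 0L) {
      x <- meanPoolImages(x, dim(x)[2L] %/% model$inputSize)
    } else {
      stop("image size ", dim(x)[2L], " incompatible with classifier input ",
           model$inputSize)
    }
  }
  fw <- classifierForward(model$params, model$config, x)
  list(probs = nnSoftmaxRows(fw$logits), features = fw$features)
}

#' Classification accuracy on a labeled set
#' @param model a trained classifier.
#' @param dataset a [LabeledImageSet-class].
#' @return Fraction of images whose argmax prediction matches the label.
#' @export
classifierAccuracy <- function(model, dataset) {
  pr <- predictClassifier(model, dataset)
  mean(max.col(pr$probs) - 1L == imageLabels(dataset))
}

#' Wrap a classifier as a pluggable feature encoder
#'
#' The encoder interface used by [extractFeatures()], [frechetDistance()]
#' inputs and [privacyAudit()]: any list with fields `fn(images) ->
#' feature matrix`, `tag`, `dim`, `inputSize` plugs in; this wraps the
#' penultimate (pooled) layer of a trained phantom classifier. Metric values
#' are encoder-tagged and never comparable across encoders.
#'
#' @param model a trained classifier.
#' @param tag short identifier recorded in metric reports.
#' @return An encoder list.
#' @export
classifierEncoder <- function(model, tag = "phantom-cnn") {
  force(model)
  list(fn = function(images) predictClassifier(model, images)$features,
       tag = tag,
       dim = nrow(model$params$head.W),
       inputSize = model$inputSize)
}
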