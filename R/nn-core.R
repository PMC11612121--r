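# Minimal neural-network primitives on base BLAS matrix operations.
# Every layer exposes a forward returning (out, cache) and a backward taking
# (grad_out, cache) and returning gradients; models compose these explicitly.
# Parameters live in flat named lists of matrices/vectors so the optimizer,
# EMA and checkpointing can treat them uniformly.

nnTruncNormal <- function(n, sd = 0.02) {
  # truncated at 2 sd, the ViT convention
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

nnLinearInit <- function(dIn, dOut, sd = 0.02, zero = FALSE) {
  W <- if (zero) matrix(0, dIn, dOut) else matrix(nnTruncNormal(dIn * dOut, sd), dIn, dOut)
  list(W = W, b = numeric(dOut))
}

nnLinearFwd <- function(x, W, b) {
  out <- x %*% W
  out + rep(b, each = nrow(out))
}

nnLinearBwd <- function(dy, x, W) {
  list(dW = crossprod(x, dy), db = colSums(dy), dx = tcrossprod(dy, W))
}

# tanh approximation of GELU (the standard fast variant); the cached
# variants reuse the forward tanh in the backward pass
nnGeluFwd <- function(x) {
  0.5 * x * (1 + tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
}

nnGeluFwdC <- function(x) {
  t <- tanh(0.7978845608028654 * (x + 0.044715 * x^3))
  list(out = 0.5 * x * (1 + t), t = t)
}

nnGeluBwdC <- function(dy, x, t) {
  dy * (0.5 * (1 + t) +
          0.5 * x * (1 - t^2) * 0.7978845608028654 * (1 + 3 * 0.044715 * x^2))
}

nnGeluBwd <- function(dy, x) {
  nnGeluBwdC(dy, x, tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
}

nnSiluFwd <- function(x) x / (1 + exp(-x))

nnSiluBwd <- function(dy, x) {
  s <- 1 / (1 + exp(-x))
  dy * (s + x * s * (1 - s))
}

nnSigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise layer norm without learnable affine (the adaLN design regresses
# scale/shift from the conditioning signal instead).
nnLayerNormFwd <- function(x, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * invstd
  list(out = xhat, xhat = xhat, invstd = invstd)
}

nnLayerNormBwd <- function(dy, cache) {
  xhat <- cache$xhat
  m1 <- rowMeans(dy)
  m2 <- rowMeans(dy * xhat)
  cache$invstd * (dy - m1 - xhat * m2)
}

nnSoftmaxRows <- function(x) {
  x <- x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x)
  e / rowSums(e)
}

nnSoftmaxRowsBwd <- function(dy, p) {
  p * (dy - rowSums(dy * p))
}

# --- optimizer ---------------------------------------------------------------

#' @keywords internal
nnAdamInit <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# AdamW step: decoupled weight decay, bias-corrected moments.
nnAdamStep <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weightDecay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Exponential moving average update of a parameter set
#'
#' Applies `ema' = decay * ema + (1 - decay) * w` elementwise to every
#' parameter tensor. With `decay = 0` the average tracks the raw weights
#' exactly; with `decay = 1` it never moves.
#'
#' @param emaParams named list of EMA parameter tensors.
#' @param params named list of current parameter tensors (same shapes).
#' @param decay decay rate in `[0, 1]`.
#' @return Updated named list of EMA parameters.
#' @export
emaUpdate <- function(emaParams, params, decay) {
  stopifnot(decay >= 0, decay <= 1, identical(names(emaParams), names(params)))
  for (nm in names(params)) {
    if (!identical(dim(emaParams[[nm]]), dim(params[[nm]])) ||
        length(emaParams[[nm]]) != length(params[[nm]])) {
      stop("emaUpdate: shape mismatch for parameter '", nm, "'")
    }
    emaParams[[nm]] <- decay * emaParams[[nm]] + (1 - decay) * params[[nm]]
  }
  emaParams
}

# Finite-difference gradient check helper used by the test suite: compares
# analytic gradients of `lossFn(params)` (returning list(loss, grads)) against
# central differences on a random subsample of coordinates.
nnGradCheck <- function(params, lossFn, nProbe = 25L, h = 1e-4, seed = 1L) {
  set.seed(seed)
  ref <- lossFn(params)
  out <- data.frame(name = character(), analytic = numeric(), numeric = numeric())
  nms <- names(params)[vapply(names(params), function(nm) !is.null(ref$grads[[nm]]), TRUE)]
  for (k in seq_len(nProbe)) {
    nm <- sample(nms, 1L)
    i <- sample(length(params[[nm]]), 1L)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
    num <- (lossFn(pp)$loss - lossFn(pm)$loss) / (2 * h)
    out <- rbind(out, data.frame(name = nm, analytic = ref$grads[[nm]][i],
                                 numeric = num))
  }
  out
}
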