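#' Extract feature embeddings with a pluggable encoder
#'
#' Applies the encoder's penultimate-layer map to every image (after mean
#' pooling to the encoder's input size when the image side is an integer
#' multiple of it) and returns one feature row per image. Deterministic in
#' inference mode.
#'
#' @param images a [LabeledImageSet-class] or `N x H x W` array.
#' @param encoder an encoder list, e.g. from [classifierEncoder()].
#' @return A list of class `FeatureEmbeddings` with `vectors` (`N x D`),
#'   `ids`, and `tag`.
#' @export
extractFeatures <- function(images, encoder) {
  ids <- if (is(images, "LabeledImageSet")) imageIds(images) else
    sprintf("img-%06d", seq_len(dim(asImageArray(images))[1L]))
  v <- encoder$fn(images)
  if (!all(is.finite(v))) stop("encoder produced non-finite features")
  structure(list(vectors = v, ids = ids, tag = encoder$tag),
            class = "FeatureEmbeddings")
}

#' Inception Score
#'
#' `exp` of the mean row-wise Kullback-Leibler divergence between the
#' per-image class distribution `p(y|x)` and the marginal `p(y)` (the column
#' mean); `0 log 0` is treated as 0. Lies in `[1, K]`. Computed on the full
#' set by default; `splits > 1` averages the score over consecutive splits.
#'
#' @param probs `N x K` matrix of class-probability rows.
#' @param splits number of splits (default 1: full-set score).
#' @return Scalar score (mean over splits).
#' @export
inceptionScore <- function(probs, splits = 1L) {
  probs <- as.matrix(probs)
  if (ncol(probs) < 2L) stop("need K >= 2 classes")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1 within 1e-6")
  one <- function(pm) {
    py <- colMeans(pm)
    lr <- log(sweep(pm, 2L, py, "/"))
    lr[pm == 0] <- 0
    exp(mean(rowSums(pm * lr)))
  }
  if (splits <= 1L) return(one(probs))
  grp <- cut(seq_len(nrow(probs)), splits, labels = FALSE)
  mean(vapply(split.data.frame(probs, grp), one, 0))
}

#' Frechet distance between Gaussian feature summaries
#'
#' `frechetDistance` fits means and (unbiased) covariances to two feature
#' sets and evaluates
#' `||mu_X - mu_Y||^2 + tr(S_X + S_Y - 2 (S_X S_Y)^{1/2})`.
#' The matrix square root is taken on the symmetrized product
#' `S_X^{1/2} S_Y S_X^{1/2}`; eigenvalues in `[-tol, 0)` are clipped to zero
#' and more negative ones are an error.
#'
#' @param featsReal,featsGen `FeatureEmbeddings` or plain `N x D` matrices.
#' @return Scalar distance (>= 0 up to the clipping tolerance).
#' @export
frechetDistance <- function(featsReal, featsGen) {
  fx <- if (inherits(featsReal, "FeatureEmbeddings")) featsReal$vectors else as.matrix(featsReal)
  fy <- if (inherits(featsGen, "FeatureEmbeddings")) featsGen$vectors else as.matrix(featsGen)
  if (ncol(fx) != ncol(fy)) stop("feature dimensions differ")
  if (nrow(fx) <= ncol(fx) || nrow(fy) <= ncol(fy))
    warning("fewer samples than feature dimensions: covariance estimates are singular")
  frechetFromMoments(colMeans(fx), stats::cov(fx), colMeans(fy), stats::cov(fy))
}

#' @rdname frechetDistance
#' @param mu1,mu2 mean vectors (scalars allowed for 1-D).
#' @param S1,S2 covariance matrices (scalars allowed for 1-D).
#' @param tol negative-eigenvalue clipping tolerance for the matrix square
#'   root (relative to the largest eigenvalue magnitude).
#' @export
frechetFromMoments <- function(mu1, S1, mu2, S2, tol = 1e-6) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  dmu <- sum((mu1 - mu2)^2)
  e1 <- eigen(S1, symmetric = TRUE)
  sq1 <- e1$vectors %*% (sqrt(pmax(e1$values, 0)) * t(e1$vectors))
  Bm <- sq1 %*% S2 %*% sq1
  ev <- eigen((Bm + t(Bm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scaleRef <- max(1, abs(ev))
  if (any(ev < -tol * scaleRef))
    stop("matrix square root failed: eigenvalue ", min(ev),
         " below the clipping tolerance")
  trSqrt <- sum(sqrt(pmax(ev, 0)))
  dmu + sum(diag(S1)) + sum(diag(S2)) - 2 * trSqrt
}
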