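# Non-overlapping patch extraction and its exact inverse.
#
# Batched arrays are [B, H, W, C]. Patch rows are ordered row-major over the
# patch grid (left-to-right, then top-to-bottom) and sample-major (all tokens
# of sample 1, then sample 2, ...). Within a token, the p x p x C patch is
# flattened column-major over (py, px, channel).

imPatchify <- function(x, p) {
  d <- dim(x)
  B <- d[1L]; h <- d[2L]; w <- d[3L]; C <- d[4L]
  if (h %% p != 0L || w %% p != 0L)
    stop("spatial dimensions must be divisible by the patch size")
  gh <- h %/% p; gw <- w %/% p
  a <- array(x, c(B, p, gh, p, gw, C))
  a <- aperm(a, c(5L, 3L, 1L, 2L, 4L, 6L))  # (gx, gy, b, py, px, c)
  dim(a) <- c(gw * gh * B, p * p * C)
  a
}

imUnpatchify <- function(tok, p, channels, B) {
  n <- nrow(tok)
  Tn <- n %/% B
  g <- sqrt(Tn)
  if (g %% 1 != 0) stop("token count per sample must be a perfect square")
  g <- as.integer(g)
  if (ncol(tok) != p * p * channels)
    stop("token width must equal p^2 * channels")
  a <- array(tok, c(g, g, B, p, p, channels))
  a <- aperm(a, c(3L, 4L, 2L, 5L, 1L, 6L))  # (b, py, gy, px, gx, c)
  dim(a) <- c(B, g * p, g * p, channels)
  a
}

#' Split a latent into a sequence of flattened patches
#'
#' Cuts an `H x W x C` latent (or `H x W` matrix) into non-overlapping
#' `p x p` patches in row-major grid order and flattens each into one row, so
#' a `64 x 64 x 4` latent with `p = 2` yields `1024` tokens of width 16.
#' [unpatchify()] is its exact inverse.
#'
#' @param latent `H x W x C` array or `H x W` matrix; `H`, `W` divisible by `p`.
#' @param p patch size.
#' @return A `(H/p)(W/p) x p^2 C` matrix of flattened patches.
#' @export
patchify <- function(latent, p) {
  if (is.matrix(latent)) dim(latent) <- c(dim(latent), 1L)
  d <- dim(latent)
  x <- array(latent, c(1L, d))
  imPatchify(x, p)
}

#' @rdname patchify
#' @param tokens matrix of flattened per-token outputs (rows in row-major grid
#'   order); the token width determines `p^2 * channels`.
#' @param channels number of output channels per token (e.g. `2C` for a
#'   denoiser head emitting noise and covariance channels).
#' @return `unpatchify` returns an `H x W x channels` array.
#' @export
unpatchify <- function(tokens, p, channels) {
  out <- imUnpatchify(tokens, p, channels, 1L)
  array(out, dim(out)[2:4])
}

# 2-D fixed sinusoidal positional embedding for a g x g token grid,
# row-major token order; dim D split evenly between the y and x coordinates.
posEmbed2D <- function(g, D) {
  stopifnot(D %% 4 == 0)
  quarter <- D %/% 4L
  freqs <- 1 / (10000^((seq_len(quarter) - 1) / quarter))
  emb1 <- function(pos) {  # length(pos) x D/2
    ang <- outer(pos, freqs)
    cbind(sin(ang), cos(ang))
  }
  gy <- rep(seq_len(g) - 1L, each = g)   # row-major: x fastest
  gx <- rep(seq_len(g) - 1L, times = g)
  cbind(emb1(gy), emb1(gx))
}

# mean-pool an [N, H, W] stack by an integer factor (encoder preprocessing)
meanPoolImages <- function(imgs, factor) {
  if (factor == 1L) return(imgs)
  d <- dim(imgs)
  stopifnot(d[2L] %% factor == 0L, d[3L] %% factor == 0L)
  x <- array(imgs, c(d[1L], d[2L], d[3L], 1L))
  tok <- imPatchify(x, factor)
  pooled <- rowMeans(tok)
  a <- imUnpatchify(matrix(pooled, ncol = 1L), 1L, 1L, d[1L])
  array(a, c(d[1L], d[2L] %/% factor, d[3L] %/% factor))
}

#' Mean-pool a LabeledImageSet by an integer factor
#'
#' Speckle-suppressing downsampling used as encoder/classifier
#' preprocessing.
#'
#' @param x a [LabeledImageSet-class].
#' @param factor integer pooling factor dividing the image side.
#' @return A [LabeledImageSet-class] of pooled images.
#' @export
poolImageSet <- function(x, factor) {
  LabeledImageSet(meanPoolImages(imageData(x), as.integer(factor)),
                  imageLabels(x), imageIds(x))
}
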