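#' Build a rating count matrix from long-format ratings
#'
#' @param ratings data.frame with columns `item_id`, `rater_id`, `category`.
#' @return Integer `items x categories` count matrix (rows sum to the fixed
#'   number of raters).
#' @export
ratingMatrix <- function(ratings) {
  stopifnot(all(c("item_id", "rater_id", "category") %in% names(ratings)))
  tab <- table(ratings$item_id, ratings$category)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  if (length(unique(rowSums(m))) != 1L)
    stop("unequal rater counts across items")
  m
}

#' Fleiss' kappa for fixed-rater categorical agreement
#'
#' Per-item agreement `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, mean observed
#' agreement `Pbar`, expected agreement `PbarE = sum_j p_j^2` from the
#' category marginals, and `kappa = (Pbar - PbarE) / (1 - PbarE)`.
#'
#' @param counts `N x K` matrix of per-item category counts; every row must
#'   sum to the same number of raters `n >= 2`.
#' @return A list of class `KappaResult` with `kappa`, `pBar`, `pBarE`,
#'   `band`, `nItems`, `nRaters`.
#' @export
fleissKappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 items and 2 categories")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- rowSums(counts)
  if (length(unique(n)) != 1L)
    stop("unequal row sums: the design requires a fixed rater count per item")
  n <- n[1L]
  if (n < 2L) stop("need at least 2 raters")
  N <- nrow(counts)
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  pBar <- mean(Pi)
  pj <- colSums(counts) / (N * n)
  pBarE <- sum(pj^2)
  kappa <- (pBar - pBarE) / (1 - pBarE)
  structure(list(kappa = kappa, pBar = pBar, pBarE = pBarE,
                 band = kappaBand(kappa), nItems = N, nRaters = n),
            class = "KappaResult")
}

#' @export
print.KappaResult <- function(x, ...) {
  cat(sprintf("Fleiss' kappa = %.3f (%s); Pbar = %.3f, PbarE = %.3f, %d items x %d raters\n",
              x$kappa, x$band, x$pBar, x$pBarE, x$nItems, x$nRaters))
  invisible(x)
}

#' Agreement band of a kappa value
#'
#' Six-band verbal scale: 0.81-1.00 almost perfect, 0.61-0.80 substantial,
#' 0.41-0.60 moderate, 0.21-0.40 fair, 0.01-0.20 slight, and 0 or less no
#' agreement. Band boundaries are closed on the lower edge (0.81 is "almost
#' perfect").
#'
#' @param kappa numeric, `<= 1`.
#' @return Character band label.
#' @export
kappaBand <- function(kappa) {
  if (kappa > 1 + 1e-12) stop("kappa cannot exceed 1")
  if (kappa <= 0) "no agreement"
  else if (kappa < 0.21) "slight agreement"
  else if (kappa < 0.41) "fair agreement"
  else if (kappa < 0.61) "moderate agreement"
  else if (kappa < 0.81) "substantial agreement"
  else "almost perfect agreement"
}

# DeLong structural components: V10 (per positive) and V01 (per negative)
delongComponents <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp),
       auc = mean(cmp), nPos = length(pos), nNeg = length(neg))
}

#' Mann-Whitney AUC with a DeLong confidence interval
#'
#' `AUC = [#(pos > neg) + 0.5 #(ties)] / (nPos nNeg)`; the CI uses the
#' DeLong structural-components variance with a normal approximation,
#' clipped to `[0, 1]`.
#'
#' @param scores numeric scores (binary 0/1 allowed).
#' @param labels 0/1 labels; both classes must be present.
#' @param level confidence level (default 0.95).
#' @return A list with `auc`, `se`, `ci` (length 2), `nPos`, `nNeg`.
#' @export
aucBinary <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("need at least one positive and one negative")
  dc <- delongComponents(scores, labels)
  v <- stats::var(dc$v10) / dc$nPos + stats::var(dc$v01) / dc$nNeg
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = dc$auc, se = se,
       ci = c(max(0, dc$auc - z * se), min(1, dc$auc + z * se)),
       nPos = dc$nPos, nNeg = dc$nNeg)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two score vectors over the same labels via the
#' structural-components variance of the AUC difference; two-sided normal
#' p value.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels shared 0/1 labels.
#' @return A list with `aucA`, `aucB`, `deltaAuc`, `z`, `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(labels))
    stop("scores and labels must be paired (equal lengths)")
  da <- delongComponents(scoresA, labels)
  db <- delongComponents(scoresB, labels)
  delta <- da$auc - db$auc
  v <- stats::var(da$v10 - db$v10) / da$nPos +
       stats::var(da$v01 - db$v01) / da$nNeg
  if (v <= 0) {
    if (abs(delta) < 1e-12) {
      return(list(aucA = da$auc, aucB = db$auc, deltaAuc = delta, z = 0, p = 1))
    }
    warning("zero estimated variance with nonzero AUC difference")
    return(list(aucA = da$auc, aucB = db$auc, deltaAuc = delta,
                z = sign(delta) * Inf, p = 0))
  }
  z <- delta / sqrt(v)
  list(aucA = da$auc, aucB = db$auc, deltaAuc = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon signed-rank test (exact, tie-aware)
#'
#' Zero differences are dropped; tied absolute differences receive
#' mid-ranks. For `n <= 25` (after dropping zeros) the two-sided p value is
#' exact, from the full sign-pattern distribution of the rank sum computed
#' by dynamic programming over doubled (integer) mid-ranks; above that, a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y paired numeric vectors.
#' @return A list with `W` (positive-rank sum), `p` (two-sided), `n`
#'   (non-zero pairs), `exact` (logical).
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero")
    return(list(W = 0, p = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # distribution of 2W over all 2^n sign patterns via convolution
    w2 <- as.integer(round(2 * r))
    tot <- sum(w2)
    f <- numeric(tot + 1L)   # f[s + 1] = #patterns with doubled sum s
    f[1L] <- 1
    for (w in w2) {
      g <- numeric(tot + 1L)
      g[seq_len(tot + 1L - w) + w] <- f[seq_len(tot + 1L - w)]
      f <- f + g
    }
    probs <- f / 2^n
    s <- as.integer(round(2 * W))
    pLow <- sum(probs[seq_len(s + 1L)])
    pHigh <- sum(probs[(s + 1L):(tot + 1L)])
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(W = W, p = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  list(W = W, p = 2 * stats::pnorm(-abs(z)), n = n, exact = FALSE)
}

#' Wilson score interval with continuity correction
#'
#' The proportion confidence interval, reported in percent to one decimal,
#' with bounds clipped to `[0, 100]`.
#'
#' @param successes,n counts, `0 <= successes <= n`.
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` in percent.
#' @export
proportionCI <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 2 * (n + z^2)
  lower <- if (successes == 0) 0 else
    (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / denom
  upper <- if (successes == n) 1 else
    (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / denom
  out <- round(100 * c(lower = max(0, lower), upper = min(1, upper)), 1L)
  out
}

#' Reconstruct binary reader decisions from printed sensitivity/specificity
#'
#' Builds a `BinaryOutcomeSet` (0/1 scores + labels) whose empirical
#' sensitivity and specificity reproduce printed table rates, enabling
#' derived statistics (AUC, CIs) to be recomputed from published numbers.
#'
#' @param sens,spec rates in percent.
#' @param nPos,nNeg class sizes.
#' @param tol admissible deviation of `rate * n` from an integer, as a
#'   fraction of `n` (default 5e-4, i.e. 0.05%).
#' @return A list of class `BinaryOutcomeSet` with `scores` and `labels`.
#' @export
confusionFromRates <- function(sens, spec, nPos, nNeg, tol = 5e-4) {
  tp <- sens / 100 * nPos
  tn <- spec / 100 * nNeg
  if (abs(tp - round(tp)) > tol * nPos || abs(tn - round(tn)) > tol * nNeg)
    stop("rates do not correspond to integer counts within tolerance")
  tp <- round(tp); tn <- round(tn)
  structure(list(
    scores = c(rep(1, tp), rep(0, nPos - tp), rep(1, nNeg - tn), rep(0, tn)),
    labels = c(rep(1L, nPos), rep(0L, nNeg))),
    class = "BinaryOutcomeSet")
}
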