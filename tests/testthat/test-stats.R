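test_that("Fleiss' kappa hand-worked example and invariances", {
  r <- fleissKappa(rbind(c(3, 0), c(2, 1)))
  expect_equal(r$kappa, -0.2)
  expect_equal(r$pBar, 2 / 3)
  expect_equal(r$pBarE, 13 / 18)
  # unanimous agreement
  expect_equal(fleissKappa(rbind(c(4, 0), c(4, 0), c(0, 4)))$kappa, 1)
  # category permutation invariance
  m <- rbind(c(2, 1, 3), c(4, 1, 1), c(0, 3, 3))
  expect_equal(fleissKappa(m)$kappa, fleissKappa(m[, c(3, 1, 2)])$kappa)
  expect_error(fleissKappa(rbind(c(3, 0), c(2, 2))), "row sums")
})

test_that("Fleiss' kappa matches a pairwise-agreement oracle on random matrices", {
  # independent route: P_i as the fraction of agreeing rater pairs
  oracle <- function(m) {
    n <- sum(m[1L, ])
    Pi <- apply(m, 1L, function(r) sum(choose(r, 2)) / choose(n, 2))
    pj <- colSums(m) / sum(m)
    (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
  }
  set.seed(7)
  for (i in 1:100) {
    N <- sample(2:15, 1); K <- sample(2:5, 1); n <- sample(2:8, 1)
    m <- t(vapply(seq_len(N), function(j) {
      as.vector(rmultinom(1, n, rgamma(K, 1)))
    }, integer(K)))
    expect_equal(fleissKappa(m)$kappa, oracle(m), tolerance = 1e-12)
  }
})

test_that("kappa bands follow the six-level scale with closed lower bounds", {
  expect_equal(kappaBand(0.132), "slight agreement")
  expect_equal(kappaBand(-0.247), "no agreement")
  expect_equal(kappaBand(0.81), "almost perfect agreement")
  expect_equal(kappaBand(0.21), "fair agreement")
  expect_equal(kappaBand(0.41), "moderate agreement")
  expect_equal(kappaBand(0.61), "substantial agreement")
  expect_equal(kappaBand(0), "no agreement")
  expect_error(kappaBand(1.2), "exceed")
})

test_that("AUC equals the all-pairs count oracle, with tie handling", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- c(rep(1L, n %/% 2), rep(0L, n - n %/% 2))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cnt <- 0
    for (a in pos) for (b in neg) cnt <- cnt + (a > b) + 0.5 * (a == b)
    expect_equal(aucBinary(scores, labels)$auc,
                 cnt / (length(pos) * length(neg)))
  }
  expect_equal(aucBinary(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(aucBinary(rep(1, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(aucBinary(1:3, c(1, 1, 1)), "negative")
})

test_that("binary reader rates reproduce printed AUC values", {
  # sensitivity 86.8%, specificity 68.0% over 500/500 -> AUC 0.774
  o <- confusionFromRates(86.8, 68.0, 500L, 500L)
  expect_equal(sum(o$scores[o$labels == 1]), 434)
  expect_equal(aucBinary(o$scores, o$labels)$auc, 0.774)
  o2 <- confusionFromRates(100, 100, 50L, 50L)
  expect_equal(aucBinary(o2$scores, o2$labels)$auc, 1)
  expect_equal(sum(confusionFromRates(55.6, 50, 500L, 500L)$scores[
    confusionFromRates(55.6, 50, 500L, 500L)$labels == 1]), 278)
  expect_error(confusionFromRates(86.7, 68, 500L, 500L), "integer")
})

test_that("DeLong test: degenerate cases, symmetry, and permutation oracle", {
  set.seed(13)
  labels <- rep(c(1L, 0L), each = 10L)
  s <- runif(20)
  same <- delongTest(s, s, labels)
  expect_equal(same$deltaAuc, 0)
  expect_equal(same$p, 1)
  s2 <- runif(20)
  ab <- delongTest(s, s2, labels)
  ba <- delongTest(s2, s, labels)
  expect_equal(ab$deltaAuc, -ba$deltaAuc)
  expect_equal(ab$p, ba$p)

  # paired permutation oracle: swap the two scores within items; AUC by the
  # direct pair-count definition, independent of the implementation
  aucOf <- function(x) mean(outer(x[labels == 1], x[labels == 0],
                                  function(a, b) (a > b) + 0.5 * (a == b)))
  obs <- abs(aucOf(s) - aucOf(s2))
  set.seed(14)
  R <- 1e5L
  swaps <- matrix(runif(R * 20L) < 0.5, R, 20L)
  perm <- numeric(R)
  for (r in seq_len(R)) {
    a <- ifelse(swaps[r, ], s2, s)
    b <- ifelse(swaps[r, ], s, s2)
    perm[r] <- abs(aucOf(a) - aucOf(b))
  }
  pPerm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(ab$p - pPerm), 0.02)
})

test_that("Wilcoxon signed-rank: exact enumeration and tie/zero handling", {
  # n = 5, all positive distinct differences: p = 2/32
  expect_equal(wilcoxonSignedRank(2:6, (1:5) - 0.5)$p, 0.0625)
  expect_warning(r0 <- wilcoxonSignedRank(1:4, 1:4), "zero")
  expect_equal(r0$p, 1)

  # exhaustive sign-pattern oracle for n <= 10
  oracle <- function(d) {
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    pLow <- mean(Ws <= W + 1e-9)
    pHigh <- mean(Ws >= W - 1e-9)
    min(1, 2 * min(pLow, pHigh))
  }
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)
    d <- x - y
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxonSignedRank(d, rep(0, length(d)))$p, oracle(d))
  }
  # agreement with stats::wilcox.test in the tie-free exact regime
  set.seed(18)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxonSignedRank(x, y)$p,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("DeLong implementation agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(19)
  labels <- rep(c(1L, 0L), each = 30L)
  sA <- runif(60) + 0.3 * labels
  sB <- runif(60) + 0.25 * labels
  ours <- delongTest(sA, sB, labels)
  ref <- pROC::roc.test(pROC::roc(labels, sA, quiet = TRUE),
                        pROC::roc(labels, sB, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-8)
  ci <- aucBinary(sA, labels)
  expect_equal(ci$auc, as.numeric(pROC::auc(pROC::roc(labels, sA, quiet = TRUE))))
})

test_that("Wilson intervals with continuity correction match printed cells", {
  expect_equal(unname(proportionCI(97, 100)), c(90.8, 99.2))
  expect_equal(unname(proportionCI(42, 100)), c(32.3, 52.3))
  expect_equal(unname(proportionCI(100, 100)), c(95.4, 100.0))
  expect_equal(unname(proportionCI(0, 10))[1L], 0)
  # ordering and range invariants
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:500, 1); k <- sample(0:n, 1)
    ci <- proportionCI(k, n)
    expect_lte(ci[[1L]], 100 * k / n + 1e-9)
    expect_gte(ci[[2L]], 100 * k / n - 1e-9)
    expect_gte(ci[[1L]], 0)
    expect_lte(ci[[2L]], 100)
  }
})

test_that("rating matrices build from long format with fixed rater counts", {
  df <- data.frame(item_id = rep(c("a", "b"), each = 3),
                   rater_id = rep(1:3, 2),
                   category = c("r", "r", "r", "r", "s", "r"))
  m <- ratingMatrix(df)
  expect_equal(unname(m), rbind(c(3L, 0L), c(2L, 1L)))
  expect_equal(fleissKappa(m)$kappa, -0.2)
  expect_error(ratingMatrix(df[-1L, ]), "unequal")
})
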