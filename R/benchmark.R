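#' Assemble a real/synthetic training mix
#'
#' Samples a training set of fixed total size whose class composition
#' follows the real pool, replacing a fraction of each class with synthetic
#' images: `mixFraction = 0` reproduces an all-real sample,
#' `mixFraction = 0.5` the half-real/half-synthetic design. Real images are
#' sampled without replacement.
#'
#' @param real,synth [LabeledImageSet-class] pools.
#' @param mixFraction synthetic fraction in `[0, 1]`.
#' @param nTotal total training-set size (default: size of `real`).
#' @param seed sampling seed.
#' @return A [LabeledImageSet-class] of `nTotal` images.
#' @export
buildTrainingSets <- function(real, synth, mixFraction, nTotal = NULL,
                              seed = 1L) {
  stopifnot(mixFraction >= 0, mixFraction <= 1)
  if (is.null(nTotal)) nTotal <- length(real)
  set.seed(seed)
  realLab <- imageLabels(real)
  classes <- sort(unique(realLab))
  target <- round(nTotal * as.numeric(table(realLab)) / length(real))
  parts <- list()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    nc <- target[i]
    nS <- round(mixFraction * nc)
    nR <- nc - nS
    ridx <- which(realLab == cl)
    if (length(ridx) < nR) stop("insufficient real images for class ", cl)
    parts[[length(parts) + 1L]] <- real[sample(ridx, nR)]
    if (nS > 0L) {
      sidx <- which(imageLabels(synth) == cl)
      if (length(sidx) < nS) stop("insufficient synthetic images for class ", cl)
      parts[[length(parts) + 1L]] <- synth[sample(sidx, nS)]
    }
  }
  combineImageSets(parts)
}

#' Stratified k-fold split
#'
#' Partitions a dataset into `k` class-stratified folds (disjoint, union =
#' dataset, per-class sizes differing by at most 1).
#'
#' @param dataset a [LabeledImageSet-class].
#' @param k number of folds (default 5).
#' @param seed shuffling seed.
#' @return List of `k` integer index vectors.
#' @export
kfoldSplit <- function(dataset, k = 5L, seed = 1L) {
  labels <- imageLabels(dataset)
  if (length(labels) < k) stop("fewer items than folds")
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer than k = ", k, " members")
    idx <- sample(idx)
    asg <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[asg == f])
  }
  lapply(folds, sort)
}

#' Train a binary classifier and evaluate on a held-out real set
#'
#' Pools the positive classes (by default every label >= 1, the
#' "suspicious" analogue) against label 0, trains the residual bottleneck
#' classifier, scores the external test set, and reports AUC (Mann-Whitney
#' with DeLong CI), sensitivity and specificity at the 0.5 probability
#' threshold, and the F1 of the positive class. Errors if train and test
#' ids overlap (leakage guard).
#'
#' @param trainSet,testSet [LabeledImageSet-class] objects with disjoint ids.
#' @param config a [classifierConfig()].
#' @param positiveClasses labels pooled as the positive class.
#' @return A list with `auc`, `sensitivity`, `specificity`, `f1`, `scores`,
#'   `labels`.
#' @export
trainAndEval <- function(trainSet, testSet, config = classifierConfig(),
                         positiveClasses = NULL) {
  if (length(intersect(imageIds(trainSet), imageIds(testSet))) > 0L)
    stop("train/test id leakage detected")
  if (is.null(positiveClasses))
    positiveClasses <- setdiff(unique(c(imageLabels(trainSet),
                                        imageLabels(testSet))), 0L)
  binarize <- function(s)
    LabeledImageSet(imageData(s),
                    as.integer(imageLabels(s) %in% positiveClasses),
                    imageIds(s))
  btrain <- binarize(trainSet)
  if (length(unique(imageLabels(btrain))) < 2L)
    stop("a class is absent from the training set")
  model <- trainClassifier(btrain, config, numClasses = 2L)
  btest <- binarize(testSet)
  pr <- predictClassifier(model, btest)
  scores <- pr$probs[, 2L]
  y <- imageLabels(btest)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  list(auc = aucBinary(scores, y)$auc,
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
       scores = scores, labels = y)
}

#' Cross-validated benchmark of one training set against a fixed test set
#'
#' Stratified `k`-fold over the training pool: each fold's model trains on
#' the other `k - 1` folds and is evaluated on the same fixed external test
#' set, yielding per-fold AUC, sensitivity, specificity and F1 plus
#' mean +/- SD.
#'
#' @param trainPool a [LabeledImageSet-class] training pool.
#' @param testSet the fixed external [LabeledImageSet-class] test set.
#' @param k folds (default 5).
#' @param config a [classifierConfig()].
#' @param positiveClasses labels pooled as positive (default: all >= 1).
#' @param seed fold-assignment seed.
#' @return A list of class `CVResult` with `folds` (data.frame) and
#'   `summary` (mean and sd per metric).
#' @export
cvBenchmark <- function(trainPool, testSet, k = 5L,
                        config = classifierConfig(), positiveClasses = NULL,
                        seed = 1L) {
  folds <- kfoldSplit(trainPool, k, seed)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- sort(unlist(folds[-f]))
    fit <- trainAndEval(trainPool[trIdx], testSet, config, positiveClasses)
    res[[f]] <- data.frame(fold = f, auc = fit$auc,
                           sensitivity = fit$sensitivity,
                           specificity = fit$specificity, f1 = fit$f1)
  }
  folds_df <- do.call(rbind, res)
  metrics <- c("auc", "sensitivity", "specificity", "f1")
  structure(list(
    folds = folds_df,
    summary = data.frame(metric = metrics,
                         mean = vapply(metrics, function(m) mean(folds_df[[m]]), 0),
                         sd = vapply(metrics, function(m) stats::sd(folds_df[[m]]), 0))),
    class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat("Cross-validated benchmark:\n")
  print(x$folds, row.names = FALSE)
  cat("mean +/- SD:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare two cross-validated benchmarks
#'
#' Paired (by fold) Wilcoxon signed-rank p value for every metric.
#'
#' @param cvA,cvB `CVResult` objects with equal fold counts.
#' @return data.frame with metric, fold means of both arms, and the
#'   two-sided p value.
#' @export
compareCV <- function(cvA, cvB) {
  if (nrow(cvA$folds) != nrow(cvB$folds)) stop("fold counts differ")
  metrics <- c("auc", "sensitivity", "specificity", "f1")
  do.call(rbind, lapply(metrics, function(m) {
    p <- suppressWarnings(wilcoxonSignedRank(cvA$folds[[m]], cvB$folds[[m]])$p)
    data.frame(metric = m, meanA = mean(cvA$folds[[m]]),
               meanB = mean(cvB$folds[[m]]), p = p)
  }))
}
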