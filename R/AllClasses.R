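#' @import methods
NULL

#' LabeledImageSet: grayscale images with ordinal class labels
#'
#' The universal dataset currency of the package: `N` grayscale images in
#' `[0, 1]` stored as an `N x H x W` array, one integer class label per image
#' (0-based, mapping to the ordinal suspicion categories, e.g. BI-RADS
#' {3, 4A, 4B, 4C, 5}), and one stable unique id per image.
#'
#' @slot images numeric array of dimension `c(N, H, W)`, values in `[0, 1]`.
#' @slot labels integer vector of length `N`, values in `[0, numClasses)`.
#' @slot ids character vector of length `N`, unique.
#'
#' @export
setClass("LabeledImageSet",
  representation(images = "array", labels = "integer", ids = "character"),
  validity = function(object) {
    d <- dim(object@images)
    msgs <- character()
    if (length(d) != 3L) msgs <- c(msgs, "images must be an N x H x W array")
    if (length(d) == 3L) {
      if (d[1L] != length(object@labels))
        msgs <- c(msgs, "length(labels) must equal the number of images")
      if (d[1L] != length(object@ids))
        msgs <- c(msgs, "length(ids) must equal the number of images")
    }
    if (length(object@images) > 0L) {
      if (!all(is.finite(object@images)))
        msgs <- c(msgs, "images must be finite")
      else {
        rng <- range(object@images)
        if (rng[1L] < 0 || rng[2L] > 1)
          msgs <- c(msgs, "pixel values must lie in [0, 1]")
      }
    }
    if (anyDuplicated(object@ids)) msgs <- c(msgs, "ids must be unique")
    if (any(object@labels < 0L)) msgs <- c(msgs, "labels must be non-negative")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a LabeledImageSet
#'
#' @param images `N x H x W` numeric array in `[0, 1]`.
#' @param labels integer-like vector of 0-based class labels.
#' @param ids optional character ids (defaults to `img-000001`, ...).
#' @return A [LabeledImageSet-class] object.
#' @export
LabeledImageSet <- function(images, labels, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("img-%06d", seq_len(dim(images)[1L]))
  new("LabeledImageSet", images = images, labels = as.integer(labels),
      ids = as.character(ids))
}

#' @describeIn LabeledImageSet-class number of images
#' @param x,object a `LabeledImageSet`.
#' @export
setMethod("length", "LabeledImageSet", function(x) dim(x@images)[1L])

setGeneric("imageData", function(x) standardGeneric("imageData"))
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @describeIn LabeledImageSet-class the `N x H x W` pixel array
#' @export
setMethod("imageData", "LabeledImageSet", function(x) x@images)

#' @describeIn LabeledImageSet-class integer labels (0-based)
#' @export
setMethod("imageLabels", "LabeledImageSet", function(x) x@labels)

#' @describeIn LabeledImageSet-class image ids
#' @export
setMethod("imageIds", "LabeledImageSet", function(x) x@ids)

#' @describeIn LabeledImageSet-class subset by index or id
#' @param i index vector (integer, logical, or character ids).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  LabeledImageSet(x@images[i, , , drop = FALSE], x@labels[i], x@ids[i])
})

#' @describeIn LabeledImageSet-class display summary
#' @export
setMethod("show", "LabeledImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("LabeledImageSet: %d images of %d x %d\n", d[1L], d[2L], d[3L]))
  tab <- table(object@labels)
  cat("labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})

#' Concatenate LabeledImageSets
#'
#' @param ... `LabeledImageSet` objects with identical image dimensions.
#' @return A single combined [LabeledImageSet-class].
#' @export
combineImageSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "LabeledImageSet"))
    sets <- sets[[1L]]
  dims <- unique(lapply(sets, function(s) dim(s@images)[2:3]))
  if (length(dims) != 1L) stop("image dimensions differ between sets")
  imgs <- do.call(abind3, lapply(sets, imageData))
  LabeledImageSet(imgs, unlist(lapply(sets, imageLabels)),
                  unlist(lapply(sets, imageIds)))
}

# bind N x H x W arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  hw <- dim(arrs[[1L]])[2:3]
  n <- sum(vapply(arrs, function(a) dim(a)[1L], 0L))
  out <- array(0, c(n, hw))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k > 0L) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' NoiseSchedule: forward-diffusion variance schedule
#'
#' Defines the `T`-step Gaussian forward process: per-step variances
#' `beta_t`, retention factors `alpha_t = 1 - beta_t`, and their cumulative
#' product `alphaBar_t`, so that
#' `z_t = sqrt(alphaBar_t) z_0 + sqrt(1 - alphaBar_t) eps`.
#'
#' @slot steps integer number of diffusion steps `T`.
#' @slot beta numeric vector of length `T`, each in `(0, 1)`.
#' @slot alpha numeric vector, `1 - beta`.
#' @slot alphaBar numeric vector, cumulative product of `alpha`, strictly
#'   decreasing with `alphaBar_1 > 0.99`.
#' @export
setClass("NoiseSchedule",
  representation(steps = "integer", beta = "numeric", alpha = "numeric",
                 alphaBar = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@beta) != object@steps) msgs <- c(msgs, "length(beta) != steps")
    if (any(object@beta <= 0) || any(object@beta >= 1))
      msgs <- c(msgs, "beta must lie in (0, 1)")
    if (any(diff(object@alphaBar) >= 0))
      msgs <- c(msgs, "alphaBar must be strictly decreasing")
    if (object@alphaBar[1L] <= 0.99)
      msgs <- c(msgs, "first-step alphaBar must exceed 0.99 (near-identity)")
    if (length(msgs)) msgs else TRUE
  }
)

#' @describeIn NoiseSchedule-class display summary
#' @param object a `NoiseSchedule`.
#' @export
setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d, beta in [%.2e, %.2e], alphaBar_T = %.4g\n",
              object@steps, min(object@beta), max(object@beta),
              object@alphaBar[object@steps]))
})

setGeneric("alphaBar", function(x) standardGeneric("alphaBar"))

#' @describeIn NoiseSchedule-class cumulative signal retention `alphaBar_t`
#' @param x a `NoiseSchedule`.
#' @export
setMethod("alphaBar", "NoiseSchedule", function(x) x@alphaBar)
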