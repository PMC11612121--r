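#' Configuration for the ultrasound phantom generator
#'
#' The phantom emulates a B-mode breast ultrasound field: four horizontal
#' tissue bands (skin, subcutaneous fat, glandular tissue, retromammary
#' space) with distinct mean echogenicity, multiplied by gamma-distributed
#' speckle, containing one elliptical lesion in the gland band whose
#' morphology (margin irregularity, aspect ratio, echo contrast, posterior
#' shadowing, calcifications) varies monotonically with an ordinal class
#' label standing in for BI-RADS categories 3 through 5.
#'
#' @param imageSize image side in pixels (square images).
#' @param numClasses number of ordinal classes (>= 2).
#' @param bandFractions four fractions of image height for the
#'   skin/fat/gland/retromammary bands; must sum to 1.
#' @param bandEchogenicity four mean band intensities in `[0, 1]`.
#' @param speckleShape gamma shape of the unit-mean multiplicative speckle;
#'   larger is smoother.
#' @param lesionRadiusRange lesion radius range as a fraction of image size.
#' @param featureRanges named list of `c(min, max)` endpoints for
#'   `irregularity`, `aspect`, `contrast`, `shadow`, `calcifications`; the
#'   class-to-morphology map interpolates each range linearly in
#'   `class / (numClasses - 1)`.
#' @param jitterFraction seeded per-lesion jitter amplitude, as a fraction of
#'   one inter-class step of each feature (kept below 0.5 so the expected
#'   morphology stays monotone in class).
#' @param seed integer seed making the whole dataset a pure function of the
#'   configuration.
#' @return A list of class `PhantomConfig`.
#' @export
phantomConfig <- function(imageSize = 64L,
                          numClasses = 5L,
                          bandFractions = c(0.08, 0.27, 0.45, 0.20),
                          bandEchogenicity = c(0.80, 0.30, 0.55, 0.20),
                          speckleShape = 8,
                          lesionRadiusRange = c(0.11, 0.16),
                          featureRanges = list(
                            irregularity = c(0.02, 0.40),
                            aspect = c(0.60, 1.45),
                            contrast = c(-0.10, -0.42),
                            shadow = c(0.00, 0.60),
                            calcifications = c(0, 4)
                          ),
                          jitterFraction = 0.35,
                          seed = 20260101L) {
  stopifnot(numClasses >= 2L, length(bandFractions) == 4L,
            abs(sum(bandFractions) - 1) < 1e-8,
            all(bandEchogenicity >= 0 & bandEchogenicity <= 1),
            speckleShape > 0, length(lesionRadiusRange) == 2L,
            jitterFraction >= 0, jitterFraction < 0.5)
  need <- c("irregularity", "aspect", "contrast", "shadow", "calcifications")
  if (!all(need %in% names(featureRanges)))
    stop("featureRanges must define: ", paste(need, collapse = ", "))
  structure(list(imageSize = as.integer(imageSize),
                 numClasses = as.integer(numClasses),
                 bandFractions = bandFractions,
                 bandEchogenicity = bandEchogenicity,
                 speckleShape = speckleShape,
                 lesionRadiusRange = lesionRadiusRange,
                 featureRanges = featureRanges,
                 jitterFraction = jitterFraction,
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

# row range (inclusive) of the gland band
glandRows <- function(config) {
  h <- config$imageSize
  top <- round(h * cumsum(config$bandFractions))
  c(round(h * sum(config$bandFractions[1:2])) + 1L, top[3L])
}

#' Sample a lesion specification for a class
#'
#' Each malignancy-associated feature equals its configured range endpoint
#' interpolated at `classLabel / (numClasses - 1)`, plus bounded seeded
#' jitter (strictly smaller than one inter-class step), so expected
#' morphology is monotone non-decreasing in the class label for every
#' feature. Lesion center and size are drawn so the lesion lies fully inside
#' the gland band.
#'
#' @param classLabel integer in `[0, numClasses)`.
#' @param config a [phantomConfig()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param jitter logical; `FALSE` gives the deterministic class-conditional
#'   mean morphology (center/size still drawn).
#' @return A list of class `LesionSpec` with fields `center` (x, y in
#'   pixels), `semiAxes` (a = half-width, b = half-height), `marginIrregularity`,
#'   `aspectRatio`, `echoContrast`, `shadowStrength`, `nCalcifications`,
#'   `lobes`, `phase`, and `classLabel`.
#' @export
sampleLesionSpec <- function(classLabel, config, seed = NULL, jitter = TRUE) {
  if (!is.numeric(classLabel) || length(classLabel) != 1L ||
      classLabel < 0 || classLabel >= config$numClasses || classLabel %% 1 != 0)
    stop("classLabel must be an integer in [0, numClasses)")
  if (!is.null(seed)) set.seed(seed)
  K <- config$numClasses
  t <- classLabel / (K - 1)
  interp <- function(nm) {
    r <- config$featureRanges[[nm]]
    step <- (r[2L] - r[1L]) / (K - 1)
    val <- r[1L] + t * (r[2L] - r[1L])
    if (jitter) val <- val + stats::runif(1, -1, 1) * config$jitterFraction * abs(step) * sign(1)
    # clamp to the configured range
    min(max(val, min(r)), max(r))
  }
  irr <- interp("irregularity")
  aspect <- interp("aspect")
  contrast <- interp("contrast")
  shadow <- interp("shadow")
  ncal <- round(interp("calcifications"))

  h <- config$imageSize
  gr <- glandRows(config)
  r <- stats::runif(1, config$lesionRadiusRange[1L], config$lesionRadiusRange[2L]) * h
  a <- r / sqrt(aspect)
  b <- r * sqrt(aspect)
  # shrink if the (irregularity-expanded) lesion cannot fit in the gland band
  bMax <- (gr[2L] - gr[1L]) / 2 / (1 + irr) - 1
  if (b > bMax) {
    sc <- bMax / b
    a <- a * sc
    b <- b * sc
  }
  be <- b * (1 + irr)
  ae <- a * (1 + irr)
  cy <- stats::runif(1, gr[1L] + be + 1, gr[2L] - be - 1)
  cx <- stats::runif(1, ae + 2, h - ae - 1)
  structure(list(center = c(x = cx, y = cy),
                 semiAxes = c(a = a, b = b),
                 marginIrregularity = irr,
                 aspectRatio = aspect,
                 echoContrast = contrast,
                 shadowStrength = shadow,
                 nCalcifications = as.integer(ncal),
                 lobes = sample(5:7, 1L),
                 phase = stats::runif(1, 0, 2 * pi),
                 classLabel = as.integer(classLabel)),
            class = "LesionSpec")
}

#' Render one phantom image from a lesion specification
#'
#' Layered tissue bands are offset by the lesion's echo contrast inside an
#' elliptical mask whose boundary radius is perturbed by a sinusoidal
#' function of polar angle (amplitude = margin irregularity), a posterior
#' column below the lesion is attenuated by the shadow strength, bright
#' calcification speckles are planted inside the lesion, and the whole field
#' is multiplied by unit-mean gamma speckle, then clipped to `[0, 1]`.
#'
#' @param spec a `LesionSpec` from [sampleLesionSpec()].
#' @param config the [phantomConfig()] used to sample it.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return An `H x W` matrix in `[0, 1]`.
#' @export
renderPhantom <- function(spec, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- config$imageSize
  gr <- glandRows(config)
  cx <- spec$center[["x"]]; cy <- spec$center[["y"]]
  a <- spec$semiAxes[["a"]]; b <- spec$semiAxes[["b"]]
  if (cy - b * (1 + spec$marginIrregularity) < gr[1L] - 1 ||
      cy + b * (1 + spec$marginIrregularity) > gr[2L] + 1)
    stop("lesion outside gland band")

  # background bands
  edges <- round(h * cumsum(config$bandFractions))
  rowMean <- numeric(h)
  lo <- 1L
  for (k in 1:4) {
    rowMean[lo:edges[k]] <- config$bandEchogenicity[k]
    lo <- edges[k] + 1L
  }
  img <- matrix(rowMean, h, h)  # rows = y, cols = x

  # lesion mask with sinusoidal margin perturbation
  ys <- matrix(seq_len(h), h, h)
  xs <- matrix(seq_len(h), h, h, byrow = TRUE)
  dx <- (xs - cx) / a
  dy <- (ys - cy) / b
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  bound <- 1 + spec$marginIrregularity * sin(spec$lobes * theta + spec$phase)
  mask <- rho <= bound
  img[mask] <- img[mask] + spec$echoContrast

  # posterior shadow: attenuate below the lesion with lateral taper
  if (spec$shadowStrength > 0) {
    colW <- pmax(0, 1 - dx[1L, ]^2)  # 1 at lesion center, 0 at edges
    below <- ys > cy + b
    inCols <- abs(xs - cx) <= a
    att <- 1 - spec$shadowStrength * matrix(colW, h, h, byrow = TRUE)
    sel <- below & inCols
    img[sel] <- img[sel] * att[sel]
  }

  # calcifications: bright micro-foci inside the lesion core
  if (spec$nCalcifications > 0L) {
    core <- which(rho <= 0.7, arr.ind = TRUE)
    if (nrow(core) > 0L) {
      pick <- core[sample(nrow(core), min(spec$nCalcifications, nrow(core))), ,
                   drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        y0 <- pick[i, 1L]; x0 <- pick[i, 2L]
        yy <- pmin(pmax(y0 + (-1:1), 1L), h)
        xx <- pmin(pmax(x0 + (-1:1), 1L), h)
        img[yy, xx] <- img[yy, xx] + 0.35
      }
    }
  }

  # multiplicative speckle, unit mean
  speckle <- matrix(stats::rgamma(h * h, shape = config$speckleShape,
                                  rate = config$speckleShape), h, h)
  pmin(pmax(img * speckle, 0), 1)
}

#' Generate a balanced phantom dataset
#'
#' @param config a [phantomConfig()]; `config$seed` makes the output a pure
#'   function of the configuration.
#' @param nPerClass images per class (>= 1).
#' @return A [LabeledImageSet-class] with `nPerClass * numClasses` images.
#' @export
generatePhantoms <- function(config, nPerClass) {
  stopifnot(nPerClass >= 1)
  set.seed(config$seed)
  n <- nPerClass * config$numClasses
  h <- config$imageSize
  imgs <- array(0, c(n, h, h))
  labels <- integer(n)
  ids <- character(n)
  i <- 0L
  for (cl in seq_len(config$numClasses) - 1L) {
    for (k in seq_len(nPerClass)) {
      i <- i + 1L
      spec <- sampleLesionSpec(cl, config)
      imgs[i, , ] <- renderPhantom(spec, config)
      labels[i] <- cl
      ids[i] <- sprintf("ph-s%d-c%d-%04d", config$seed %% 1000000L, cl, k)
    }
  }
  LabeledImageSet(imgs, labels, ids)
}

#' Write / read a LabeledImageSet as 8-bit PNGs with a CSV manifest
#'
#' `writeImageSet` stores one grayscale PNG per image plus `manifest.csv`
#' (columns `id,filename,label`). `readImageSet` reverses it; pixels round-trip
#' within the 8-bit quantization bound `1/255`.
#'
#' @param x a [LabeledImageSet-class].
#' @param dir directory to write to / read from (created if missing).
#' @return `writeImageSet` returns `dir` invisibly; `readImageSet` returns a
#'   [LabeledImageSet-class].
#' @export
writeImageSet <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fns <- paste0(imageIds(x), ".png")
  for (i in seq_len(length(x))) {
    png::writePNG(imageData(x)[i, , ], file.path(dir, fns[i]))
  }
  utils::write.csv(data.frame(id = imageIds(x), filename = fns,
                              label = imageLabels(x)),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeImageSet
#' @param numClasses optional; if given, labels outside `[0, numClasses)` are
#'   a parse failure.
#' @export
readImageSet <- function(dir, numClasses = NULL) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("manifest not found: ", mf)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (!all(c("id", "filename", "label") %in% names(man)))
    stop("malformed manifest: need columns id,filename,label")
  lab <- suppressWarnings(as.integer(man$label))
  if (any(is.na(lab)) || any(lab != man$label))
    stop("malformed label in manifest: labels must be integers")
  if (!is.null(numClasses) && any(lab < 0L | lab >= numClasses))
    stop("malformed label in manifest: label out of [0, ", numClasses, ")")
  imgs <- NULL
  for (i in seq_len(nrow(man))) {
    fp <- file.path(dir, man$filename[i])
    if (!file.exists(fp)) stop("missing image file: ", fp)
    m <- png::readPNG(fp)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (is.null(imgs)) imgs <- array(0, c(nrow(man), nrow(m), ncol(m)))
    imgs[i, , ] <- m
  }
  LabeledImageSet(imgs, lab, man$id)
}
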