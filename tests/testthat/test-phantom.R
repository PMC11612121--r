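test_that("class-to-morphology interpolation hits range endpoints and is monotone", {
  cfg <- phantomConfig()
  s0 <- sampleLesionSpec(0L, cfg, seed = 1L, jitter = FALSE)
  s4 <- sampleLesionSpec(4L, cfg, seed = 1L, jitter = FALSE)
  expect_equal(s0$marginIrregularity, cfg$featureRanges$irregularity[1L])
  expect_equal(s4$shadowStrength, cfg$featureRanges$shadow[2L])
  # jitter-free per-class contrast magnitudes are strictly increasing
  contr <- vapply(0:4, function(cl)
    abs(sampleLesionSpec(cl, cfg, seed = 10L, jitter = FALSE)$echoContrast), 0)
  expect_true(all(diff(contr) > 0))
  expect_error(sampleLesionSpec(5L, cfg), "classLabel")
  expect_error(sampleLesionSpec(-1L, cfg), "classLabel")
})

test_that("averaged sampled morphology is monotone non-decreasing in class", {
  cfg <- phantomConfig()
  means <- t(vapply(0:4, function(cl) {
    set.seed(500L + cl)
    rowMeans(vapply(1:40, function(i) {
      s <- sampleLesionSpec(cl, cfg)
      c(s$marginIrregularity, s$shadowStrength, abs(s$echoContrast))
    }, numeric(3)))
  }, numeric(3)))
  expect_true(all(diff(means[, 1L]) >= 0))  # irregularity
  expect_true(all(diff(means[, 2L]) >= 0))  # shadow
  expect_true(all(diff(means[, 3L]) >= 0))  # echo contrast magnitude
})

test_that("rendering is deterministic and geometrically correct", {
  cfg <- phantomConfig()
  spec <- sampleLesionSpec(2L, cfg, seed = 9L)
  img1 <- renderPhantom(spec, cfg, seed = 11L)
  img2 <- renderPhantom(spec, cfg, seed = 11L)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))

  # irregularity 0: lesion pixel count within 10% of the ellipse area
  spec$marginIrregularity <- 0
  h <- cfg$imageSize
  ys <- matrix(seq_len(h), h, h); xs <- matrix(seq_len(h), h, h, byrow = TRUE)
  rho <- sqrt(((xs - spec$center[["x"]]) / spec$semiAxes[["a"]])^2 +
                ((ys - spec$center[["y"]]) / spec$semiAxes[["b"]])^2)
  area <- sum(rho <= 1)
  expect_lt(abs(area / (pi * prod(spec$semiAxes)) - 1), 0.1)

  # zero shadow: the sub-lesion column matches flanking gland columns
  # within speckle standard error
  spec0 <- sampleLesionSpec(2L, cfg, seed = 21L, jitter = FALSE)
  spec0$shadowStrength <- 0
  img <- renderPhantom(spec0, cfg, seed = 22L)
  cx <- spec0$center[["x"]]; a <- spec0$semiAxes[["a"]]
  below <- (ceiling(spec0$center[["y"]] + spec0$semiAxes[["b"]]) + 2L):
    sonodit:::glandRows(cfg)[2L]
  sub <- img[below, round(cx + (-2:2))]
  flank <- img[below, c(round(cx - a - (3:5)), round(cx + a + (3:5)))]
  se <- sd(flank) * sqrt(1 / length(sub) + 1 / length(flank))
  expect_lt(abs(mean(sub) - mean(flank)), 4 * se)
})

test_that("a lesion spec outside the gland band is rejected", {
  cfg <- phantomConfig()
  spec <- sampleLesionSpec(1L, cfg, seed = 2L)
  spec$center[["y"]] <- 3  # skin band
  expect_error(renderPhantom(spec, cfg, seed = 1L), "gland band")
})

test_that("generatePhantoms is balanced, reproducible and labeled", {
  cfg <- phantomConfig(imageSize = 32L, seed = 77L)
  ds <- generatePhantoms(cfg, 10L)
  expect_s4_class(ds, "LabeledImageSet")
  expect_equal(length(ds), 50L)
  expect_equal(as.vector(table(imageLabels(ds))), rep(10L, 5L))
  ds2 <- generatePhantoms(cfg, 10L)
  expect_identical(imageData(ds), imageData(ds2))
  expect_false(identical(imageData(ds),
                         imageData(generatePhantoms(phantomConfig(imageSize = 32L,
                                                                  seed = 78L), 10L))))
})

test_that("PNG round trip preserves labels exactly and pixels to 8-bit", {
  ds <- generatePhantoms(phantomConfig(imageSize = 16L, seed = 4L), 4L)
  dir <- withr::local_tempdir()
  writeImageSet(ds, dir)
  back <- readImageSet(dir, numClasses = 5L)
  expect_identical(imageLabels(back), imageLabels(ds))
  expect_identical(imageIds(back), imageIds(ds))
  expect_lte(max(abs(imageData(back) - imageData(ds))), 1 / 255 + 1e-12)
})

test_that("reader errors are explicit: missing manifest, missing file, bad label", {
  empty <- withr::local_tempdir()
  expect_error(readImageSet(empty), "manifest not found")

  ds <- generatePhantoms(phantomConfig(imageSize = 16L, seed = 4L), 2L)
  dir <- withr::local_tempdir()
  writeImageSet(ds, dir)
  gone <- imageIds(ds)[1L]
  file.remove(file.path(dir, paste0(gone, ".png")))
  expect_error(readImageSet(dir), paste0(gone, ".png"))

  dir2 <- withr::local_tempdir()
  writeImageSet(ds, dir2)
  man <- read.csv(file.path(dir2, "manifest.csv"))
  man$label[1L] <- 7L
  write.csv(man, file.path(dir2, "manifest.csv"), row.names = FALSE)
  expect_error(readImageSet(dir2, numClasses = 5L), "label")
})

test_that("LabeledImageSet validity and subsetting behave", {
  toy <- toyImageSet()
  expect_error(LabeledImageSet(imageData(toy) * 2, imageLabels(toy)), "0, 1")
  expect_error(LabeledImageSet(imageData(toy), imageLabels(toy),
                               rep("x", length(toy))), "unique")
  sub <- toy[c(2L, 4L)]
  expect_equal(imageIds(sub), c("toy-02", "toy-04"))
  expect_equal(length(sub), 2L)
  byId <- toy["toy-03"]
  expect_equal(imageLabels(byId), imageLabels(toy)[3L])
})
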