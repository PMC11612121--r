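# Shared fixtures, built once per test session and memoised: several suites
# reuse the same phantom sets and trained models.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# 5-class 64 x 64 phantom sets at default generator conditions
phantomTrain5 <- function(nPerClass = 200L) {
  cachedFixture(paste0("train5_", nPerClass),
                generatePhantoms(phantomConfig(), nPerClass))
}

phantomTest5 <- function(nPerClass = 40L) {
  cachedFixture(paste0("test5_", nPerClass),
                generatePhantoms(phantomConfig(seed = 20260999L), nPerClass))
}

# the 5-class phantom classifier doubling as feature encoder: trained on
# 2x2 mean-pooled images (speckle suppression), stride-2 stem
phantomClassifier5 <- function() {
  cachedFixture("clf5", {
    cc <- classifierConfig(stemPatch = 2L, epochs = 40L, learningRate = 2e-3,
                           batchSize = 64L, weightDecay = 1e-4, seed = 7L)
    trainClassifier(poolImageSet(phantomTrain5(), 2L), cc)
  })
}

# tiny deterministic image set for I/O and container tests
toyImageSet <- function(n = 6L, size = 8L, seed = 3L) {
  set.seed(seed)
  imgs <- array(stats::runif(n * size * size), c(n, size, size))
  LabeledImageSet(imgs, rep_len(0:1, n), sprintf("toy-%02d", seq_len(n)))
}

# tiny DiT model helper for structural tests
tinyDiT <- function(inputSize = 8L, channels = 2L, numClasses = 3L,
                    hiddenDim = 32L, depth = 2L, seed = 5L) {
  initDiT(ditConfig(patchSize = 2L, hiddenDim = hiddenDim, depth = depth,
                    numHeads = 2L, numClasses = numClasses),
          inputSize, channels, seed = seed)
}

# --- end-to-end study conditions: 2-class 16 x 16 lesion-crop phantoms -------
# (gland band 0.55, lesion radius fraction 0.20-0.28: the lesion-centered
# crop analogue used for all small-image experiments)
crop16Config <- function(seed) {
  phantomConfig(imageSize = 16L, numClasses = 2L,
                bandFractions = c(0.10, 0.20, 0.55, 0.15),
                lesionRadiusRange = c(0.20, 0.28), seed = seed)
}

# tiny pixel-space diffusion model trained once per session
e2eCheckpoint <- function() {
  cachedFixture("e2eCkpt", {
    train <- generatePhantoms(crop16Config(42L), 200L)
    trainDiffusion(
      train,
      ditConfig(patchSize = 2L, hiddenDim = 64L, depth = 2L, numHeads = 2L,
                numClasses = 2L, mlpRatio = 2L),
      trainConfig(totalSteps = 1500L, learningRate = 1e-3, batchSize = 32L,
                  emaDecay = 0.995, seed = 11L))
  })
}

# independent judge classifier, never exposed to the generator
e2eJudge <- function() {
  cachedFixture("e2eJudge", {
    trainClassifier(
      generatePhantoms(crop16Config(777L), 300L),
      classifierConfig(stemPatch = 2L, epochs = 40L, learningRate = 2e-3,
                       batchSize = 64L, seed = 5L))
  })
}

# guided samples per class at a given guidance strength (memoised)
e2eSamples <- function(omega, cl, n = 100L) {
  cachedFixture(sprintf("e2eS_%g_%d", omega, cl),
                sampleImages(e2eCheckpoint(), cl, n,
                             samplerConfig(steps = 50L, omega = omega,
                                           seed = 30L + cl)))
}
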