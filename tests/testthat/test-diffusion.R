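test_that("linear schedule endpoints and monotonicity", {
  sch <- noiseSchedule(1000L, "linear")
  expect_equal(alphaBar(sch)[1L], 1 - 1e-4)       # first-step identity
  expect_true(all(diff(alphaBar(sch)) < 0))
  expect_lt(alphaBar(sch)[1000L], 0.01)
  cos <- noiseSchedule(1000L, "cosine")
  expect_true(all(diff(alphaBar(cos)) < 0))
  expect_gt(alphaBar(cos)[1L], 0.99)
  expect_error(noiseSchedule(1000L, "quadratic"))
})

test_that("qSample implements the forward marginal exactly", {
  sch <- noiseSchedule(1000L)
  z0 <- array(0, c(2, 4, 4, 1))
  ones <- array(1, dim(z0))
  # alphaBar = 0.25 -> entries are sqrt(0.75)
  t25 <- which.min(abs(alphaBar(sch) - 0.25))
  ab <- alphaBar(sch)[t25]
  zt <- qSample(z0, t25, ones, sch)
  expect_equal(unique(as.vector(zt)), sqrt(1 - ab))
  # near-identity first step
  x <- array(rnorm(32), dim(z0))
  expect_equal(qSample(x, 1L, ones, sch), sqrt(1 - 1e-4) * x + 0.01 * ones,
               tolerance = 1e-12)
  expect_error(qSample(x, 0L, ones, sch), "range")
  expect_error(qSample(x, 1001L, ones, sch), "range")
})

test_that("forward marginal moments match the closed form (Monte Carlo)", {
  sch <- noiseSchedule(1000L)
  t <- 400L
  ab <- alphaBar(sch)[t]
  z0val <- 0.7
  n <- 1e4L
  set.seed(6)
  draws <- qSample(array(z0val, c(n, 1, 1, 1)), rep(t, n),
                   array(rnorm(n), c(n, 1, 1, 1)), sch)
  seMean <- sqrt(1 - ab) / sqrt(n)
  expect_lt(abs(mean(draws) - sqrt(ab) * z0val), 3 * seMean)
  seVar <- (1 - ab) * sqrt(2 / (n - 1))
  expect_lt(abs(var(as.vector(draws)) - (1 - ab)), 3 * seVar)
})

test_that("simple loss is the elementwise MSE with batch symmetry", {
  a <- array(rnorm(24), c(2, 3, 4))
  expect_equal(lossSimple(a, a), 0)
  expect_equal(lossSimple(a + 1, a), 1)
  perm <- a[2:1, , , drop = FALSE]
  expect_equal(lossSimple(a, a * 0), lossSimple(perm, perm * 0))
  expect_error(lossSimple(a, array(0, c(3, 2, 4))), "shape")
})

test_that("EMA update follows the decay formula", {
  ema <- list(w = matrix(0, 2, 2))
  w <- list(w = matrix(2, 2, 2))
  expect_equal(emaUpdate(ema, w, 0)$w, w$w)
  expect_equal(emaUpdate(ema, w, 1)$w, ema$w)
  expect_equal(emaUpdate(ema, w, 0.5)$w, matrix(1, 2, 2))
  expect_error(emaUpdate(ema, list(w = matrix(0, 3, 2)), 0.5), "shape")
})

test_that("classifier-free guidance combination specializes correctly", {
  a <- array(rnorm(8), c(2, 2, 2))
  b <- array(rnorm(8), c(2, 2, 2))
  expect_identical(cfgCombine(a, b, 0), a)
  expect_equal(cfgCombine(a, a, 0.8), a)
  expect_equal(cfgCombine(array(1, c(1, 1, 1)), array(0, c(1, 1, 1)), 0.8),
               array(1.8, c(1, 1, 1)))
  expect_error(cfgCombine(a, array(0, c(2, 2)), 0.8), "shape")
  expect_error(cfgCombine(a, b, -0.1))
})

test_that("DDIM inverts the forward construction and is self-consistent", {
  sch <- noiseSchedule(1000L)
  set.seed(12)
  z0 <- array(rnorm(32), c(2, 4, 4, 1))
  eps <- array(rnorm(32), dim(z0))
  zt <- qSample(z0, 1000L, eps, sch)
  expect_equal(ddimStep(zt, eps, 1000L, 0L, sch), z0, tolerance = 1e-10)
  # determinism at eta = 0
  expect_identical(ddimStep(zt, eps, 1000L, 500L, sch),
                   ddimStep(zt, eps, 1000L, 500L, sch))
  # two-step path with the perfect-noise oracle equals one-step
  z500 <- ddimStep(zt, eps, 1000L, 500L, sch)
  expect_equal(ddimStep(z500, eps, 500L, 0L, sch), z0, tolerance = 1e-10)
  expect_error(ddimStep(zt, eps, 500L, 500L, sch), "timestep")
})

test_that("an untrained (zero-output) model rescales by the alphaBar ratio", {
  sch <- noiseSchedule(1000L)
  set.seed(2)
  zt <- array(rnorm(16), c(1, 4, 4, 1))
  out <- ddimStep(zt, zt * 0, 800L, 300L, sch)
  expect_equal(out, sqrt(alphaBar(sch)[300L] / alphaBar(sch)[800L]) * zt)
})

test_that("training smoke run reduces the loss and honors label dropout", {
  ds <- generatePhantoms(phantomConfig(imageSize = 16L, numClasses = 2L,
                                       seed = 42L), 30L)
  dcfg <- ditConfig(patchSize = 2L, hiddenDim = 32L, depth = 2L,
                    numHeads = 2L, numClasses = 2L)
  tc <- trainConfig(totalSteps = 200L, learningRate = 1e-3, batchSize = 16L,
                    emaDecay = 0.99, seed = 11L)
  ck <- trainDiffusion(ds, dcfg, tc)
  expect_lt(mean(tail(ck$lossHistory, 50L)),
            mean(head(ck$lossHistory, 50L)))
  expect_s3_class(ck, "DiffusionCheckpoint")

  # ema decay 0 keeps EMA equal to the raw weights
  tc0 <- trainConfig(totalSteps = 5L, learningRate = 1e-3, batchSize = 8L,
                     emaDecay = 0, seed = 11L)
  ck0 <- trainDiffusion(ds, dcfg, tc0)
  expect_equal(ck0$emaParams, ck0$params)

  # label dropout 1: the label table row for real classes receives no
  # gradient, so it stays at its initialization
  dcfgDrop <- ditConfig(patchSize = 2L, hiddenDim = 32L, depth = 2L,
                        numHeads = 2L, numClasses = 2L, labelDropoutProb = 1)
  ck1 <- trainDiffusion(ds, dcfgDrop, tc0)
  init <- initDiT(dcfgDrop, 16L, 1L, seed = tc0$seed)
  expect_equal(ck1$params$label.E[1:2, ], init$params$label.E[1:2, ])
  expect_false(isTRUE(all.equal(ck1$params$label.E[3L, ],
                                init$params$label.E[3L, ])))
  expect_error(trainDiffusion(ds[0], dcfg, tc0), "empty")
})

test_that("sampling is deterministic per seed and records sampler metadata", {
  ds <- generatePhantoms(phantomConfig(imageSize = 16L, numClasses = 2L,
                                       seed = 42L), 20L)
  dcfg <- ditConfig(patchSize = 2L, hiddenDim = 32L, depth = 2L,
                    numHeads = 2L, numClasses = 2L)
  tc <- trainConfig(totalSteps = 50L, learningRate = 1e-3, batchSize = 8L,
                    emaDecay = 0.9, seed = 13L)
  ck <- cachedFixture("smokeCkpt", trainDiffusion(ds, dcfg, tc))
  sc <- samplerConfig(steps = 10L, omega = 0.8, seed = 21L)
  s1 <- sampleImages(ck, 1L, 3L, sc)
  s2 <- sampleImages(ck, 1L, 3L, sc)
  expect_identical(imageData(s1), imageData(s2))
  expect_equal(imageLabels(s1), rep(1L, 3L))
  # defaults honored in metadata
  def <- samplerConfig()
  expect_equal(def$steps, 250L)
  expect_equal(def$omega, 0.8)
  expect_identical(attr(s1, "samplerConfig"), sc)
  # missing EMA weights fall back to raw with a warning
  ck2 <- ck; ck2$emaParams <- NULL
  expect_warning(sampleImages(ck2, 0L, 1L, sc), "EMA")
})

test_that("the covariance-channel variational term is finite and trains only sigma", {
  ds <- generatePhantoms(phantomConfig(imageSize = 16L, numClasses = 2L,
                                       seed = 42L), 10L)
  dcfg <- ditConfig(patchSize = 2L, hiddenDim = 32L, depth = 2L,
                    numHeads = 2L, numClasses = 2L)
  tc <- trainConfig(totalSteps = 20L, learningRate = 1e-3, batchSize = 8L,
                    emaDecay = 0.9, trainSigma = TRUE, seed = 3L)
  ck <- trainDiffusion(ds, dcfg, tc)
  expect_true(all(is.finite(ck$lossHistory)))
})
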