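# sonodit

Class-conditional latent diffusion with a transformer denoiser for
breast-ultrasound-like image synthesis, and the complete evaluation
methodology that surrounds such a generator — implemented end-to-end in R
with no deep-learning framework.

## Who this is for

Researchers who want a fully inspectable, desk-scale reference
implementation of the synthetic-medical-imaging program: train a
conditional diffusion model on labeled grayscale images, generate images
conditioned on an ordinal malignancy-suspicion category (a BI-RADS
3/4A/4B/4C/5 analogue), and then evaluate the result the way that program
demands — distributional image metrics, a memorization (privacy) audit,
reader-study statistics, and a "does synthetic data actually help a
classifier" benchmark. Because clinical ultrasound corpora are private,
the package ships a procedural phantom generator so every stage runs from
nothing on one CPU.

## What is inside

**The generator.**

* Forward diffusion `z_t = sqrt(ab_t) z0 + sqrt(1 - ab_t) eps` over
  `T = 1000` steps (linear or cosine `beta_t` schedule).
* A diffusion-transformer denoiser: patch embedding (`p = 2`), fixed 2-D
  sinusoidal positions, adaLN-Zero blocks (conditioning regressed onto
  layer-norm scale/shift and zero-initialized residual gates from
  timestep + class-label embeddings), a zero-initialized head emitting
  predicted noise and covariance channels. Forward *and backward* passes
  are hand-derived on BLAS matrix ops and finite-difference-checked.
* Training with `L_simple` (noise MSE), AdamW (`lr 1e-4`, no weight
  decay), label dropout 0.1 for classifier-free guidance, horizontal
  flips, and an EMA of the weights.
* DDIM sampling (`S = 250` steps, `eta = 0`) with classifier-free
  guidance `eps~ = (1 + w) eps_cond - w eps_uncond`, `w = 0.8`.
* A small trainable patch-convolution VAE (`f` in {1, 2, 4, 8}; `f = 1`
  is an exact identity bypass for pixel-space diffusion).

**The evaluation battery.**

* `inceptionScore()` — `exp` mean KL between per-image class
  distributions and their marginal, over any class-probability matrix.
* `frechetDistance()` — Gaussian Fréchet distance between feature sets
  over a pluggable encoder (default: the penultimate layer of the
  phantom-trained residual bottleneck CNN).
* `privacyAudit()` — seeded nearest-neighbor search of synthetic images
  against the training set by cosine similarity, rank-k reports, flagging
  threshold, and an exact pixel-duplicate backstop.
* `fleissKappa()` + agreement bands, `aucBinary()` (Mann-Whitney with
  DeLong CI), `delongTest()`, exact tie-aware `wilcoxonSignedRank()`,
  Wilson `proportionCI()` with continuity correction, and
  `confusionFromRates()` to rebuild binary reader outcomes from printed
  sensitivity/specificity.
* `cvBenchmark()` / `compareCV()` — stratified 5-fold augmentation
  benchmark: all-real versus half-synthetic training sets evaluated on a
  fixed external test set, compared fold-paired by exact Wilcoxon.

**The data.**

* `phantomConfig()` / `generatePhantoms()` — layered-tissue speckle
  phantoms (skin/fat/gland/retromammary bands, gamma speckle) with one
  elliptical lesion whose margin irregularity, aspect ratio, echo
  contrast, posterior shadowing, and calcification count increase
  monotonically with the class label.
* `writeImageSet()` / `readImageSet()` — 8-bit grayscale PNGs plus a
  `manifest.csv` (`id,filename,label`), round-tripping within 1/255.

## A worked example

Train a tiny pixel-space model on 2-class 16x16 lesion-crop phantoms and
check that guided samples actually carry the requested class:

```r
library(sonodit)

crop16 <- function(seed) phantomConfig(
  imageSize = 16L, numClasses = 2L,
  bandFractions = c(0.10, 0.20, 0.55, 0.15),
  lesionRadiusRange = c(0.20, 0.28), seed = seed)

train <- generatePhantoms(crop16(42L), 200L)      # 400 images
ck <- trainDiffusion(
  train,
  ditConfig(hiddenDim = 64L, depth = 2L, numHeads = 2L,
            numClasses = 2L, mlpRatio = 2L),
  trainConfig(totalSteps = 1500L, learningRate = 1e-3,
              batchSize = 32L, emaDecay = 0.995, seed = 11L))

judge <- trainClassifier(                          # independent judge
  generatePhantoms(crop16(777L), 300L),
  classifierConfig(stemPatch = 2L, epochs = 40L, learningRate = 2e-3,
                   batchSize = 64L, seed = 5L))

s1 <- sampleImages(ck, 1L, 100L, samplerConfig(steps = 50L, omega = 0.8,
                                               seed = 31L))
mean(max.col(predictClassifier(judge, s1)$probs) - 1L == 1L)
#> [1] 0.93
```

So 93% of the 100 images sampled under the class-1 condition are assigned
class 1 by a classifier that never saw the generator — the conditional
channel works. The same session's privacy audit:

```r
enc <- classifierEncoder(judge)
privacyAudit(sampleImages(ck, "all", 100L,
                          samplerConfig(steps = 50L, seed = 77L)),
             train, enc, k = 3L, sampleSize = 100L, seed = 1L)
#> Nearest-neighbor privacy audit (encoder: phantom-cnn)
#>   audited 100 synthetic images, k = 3, threshold = 0.980
#>   max similarity 0.9944, flagged 71
```

The maximum similarity stays below 1 and the exact pixel-duplicate
backstop reports zero copies, so nothing in the sample is a memorized
training image. The large flagged count illustrates why the report always
carries the candidate list rather than a verdict: a 64-dimensional
phantom-trained encoder is coarse, so visually distinct phantoms of the
same class routinely exceed 0.98 cosine similarity — with this encoder the
threshold selects review candidates, it does not diagnose duplication.

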