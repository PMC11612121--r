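---
title: "Methods: conditional latent diffusion for ultrasound-like image synthesis and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional latent diffusion for ultrasound-like image synthesis and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sharing medical images across centers is constrained by privacy. One
proposed remedy is to train a generative model on the private corpus and
share synthetic images instead. This package implements, at desk scale and
entirely in R, the full methodology of that program for grayscale breast
ultrasound: a class-conditional latent diffusion model with a transformer
denoiser generating images conditioned on an ordinal malignancy-suspicion
label (a BI-RADS 3/4A/4B/4C/5 analogue), and the evaluation battery that
such a generator requires — sample-quality metrics (Inception Score,
Fréchet distance), a nearest-neighbor memorization audit, reader-study
statistics, and a data-augmentation benchmark.

Because clinical ultrasound corpora are private, the package carries its
own synthetic-data module: a procedural phantom whose class-controlled
lesion morphology stands in for the clinical ordinal labels. Every stage of
the pipeline trains and tests on phantoms with no external data or
pretrained weights.

# The generative model

## Forward process and objective

A latent $z_0$ is noised over $T = 1000$ steps with variances $\beta_t$
(linear $10^{-4} \to 0.02$ by default; squared-cosine available),
$\bar\alpha_t = \prod_{s\le t}(1-\beta_s)$:

$$ z_t = \sqrt{\bar\alpha_t}\, z_0 + \sqrt{1-\bar\alpha_t}\,\epsilon_t,
   \qquad \epsilon_t \sim \mathcal N(0, I). $$

The denoiser $\epsilon_\theta(z_t, t, c)$ is trained with the simple
objective $L_{\text{simple}} = \lVert \epsilon_\theta(z_t,c) - \epsilon_t
\rVert_2^2$ under the mean convention (mean over all elements), with
timesteps uniform on $[1, T]$, AdamW (learning rate $10^{-4}$, no weight
decay), horizontal-flip augmentation, and an exponential moving average
(EMA) of the denoiser weights. The network also emits covariance channels
$\Sigma_\theta$ (the head maps each token to a $p \times p \times 2C$
tensor); by default these are carried but not trained — an optional
variational-bound term (log-linear interpolation between $\beta_t$ and the
posterior variance $\tilde\beta_t$, mean detached) can train them — because
the deterministic DDIM sampler used throughout never consumes a learned
variance.

## The transformer denoiser

The latent is cut into non-overlapping $p \times p$ patches ($p = 2$),
each linearly embedded and summed with fixed 2-D sinusoidal positional
embeddings. Conditioning is a single vector per sample: a sinusoidal
timestep embedding passed through a two-layer MLP, plus a learned row of a
label table with a dedicated null row (index `numClasses`) for
classifier-free guidance. Each block follows the adaLN-Zero design: the
conditioning vector is regressed (after SiLU) onto six per-channel
modulation vectors — shift/scale for the pre-attention layer norm, a
residual gate for the attention branch, and the same triple for the MLP
branch — with the modulation projections and the final linear head
initialized to zero. Consequently the whole network is exactly the zero
function at initialization and every block is the identity on its tokens;
the tests assert this contract directly, and a finite-difference check
validates the hand-derived backpropagation through the full stack
(attention, layer norms, modulation, conditioning pathway).

Open design points resolved here:

* The conditioning mechanism is implemented solely through adaLN-Zero
  modulation; a latent-modulation notation ($z \oplus c$) describing
  conditional generation is read as an abstract description of the same
  mechanism, not a second pathway.
* Positional information uses fixed 2-D sin/cos embeddings (the
  convention of the DiT family; the choice is not load-bearing at these
  sizes).
* Label-dropout probability for guidance training defaults to 0.1, the
  convention of the classifier-free guidance literature.

## Sampling

Generation runs DDIM over a uniform strictly-decreasing subsequence of
$S$ timesteps (default $S = 250$) that always includes the terminal step:

$$ \hat z_0 = \frac{z_t - \sqrt{1-\bar\alpha_t}\,\tilde\epsilon}
  {\sqrt{\bar\alpha_t}}, \qquad
  z_{t'} = \sqrt{\bar\alpha_{t'}}\hat z_0 +
  \sqrt{1-\bar\alpha_{t'}-\sigma^2}\,\tilde\epsilon + \sigma\xi, $$

with $\sigma = 0$ ($\eta = 0$, deterministic) by default. At every step
classifier-free guidance combines a conditional and a null-label
prediction, $\tilde\epsilon = (1+\omega)\epsilon_\theta(z_t,c) -
\omega\,\epsilon_\theta(z_t)$, with guidance strength $\omega = 0.8$;
both evaluations use the EMA weights. The identity
"DDIM step with the true noise returns $z_0$ exactly" and the two-step
consistency $T \to T/2 \to 0$ are asserted to machine precision in the
tests.

## Latent stage

The latent autoencoder is a small trainable VAE: non-overlapping
$f \times f$ patch convolutions (kernel = stride = $f$) with one nonlinear
hidden layer on the encoder and decoder, a $C = 4$-channel latent,
reparameterized sampling, and objective MSE $+\ \beta\,$KL with
$\beta = 10^{-3}$ (the usual small-VAE regime). A pretrained
general-purpose VAE is deliberately not used: at desk scale a
phantom-trained encoder is preferable, and an identity/bypass mode
($f = 1$) runs the diffusion core directly in pixel space, which isolates
diffusion tests from autoencoder quality. Latents are standardized by
dataset-level mean/scale computed at diffusion-training time and stored in
the checkpoint (the latent-diffusion scaling convention; the inverse is
applied before decoding).

# The phantom generator

The phantom emulates a B-mode breast field: four horizontal bands (skin,
subcutaneous fat, gland, retromammary space) with echogenicities
(0.80, 0.30, 0.55, 0.20), multiplied by unit-mean gamma speckle (shape 8),
holding one elliptical lesion inside the gland band. Five
malignancy-associated features interpolate linearly between configured
endpoints as the class label runs over `0 .. K-1`, plus bounded seeded
jitter (0.35 of one inter-class step, so expected morphology stays
monotone in class):

| feature | benign end | malignant end | rendering |
|---|---|---|---|
| margin irregularity | 0.02 | 0.40 | sinusoidal radial boundary perturbation (5–7 lobes) |
| aspect ratio (h/w) | 0.60 | 1.45 | taller-than-wide at the malignant end |
| echo contrast | −0.10 | −0.42 | increasingly hypoechoic interior |
| posterior shadow | 0.00 | 0.60 | attenuated column below the lesion, laterally tapered |
| calcifications | 0 | 4 | bright micro-foci in the lesion core |

These are the sonographic features radiologists use in BI-RADS
assessment (shape, orientation, margin, echo pattern, posterior features);
the numeric endpoints are a modeling choice fixed once — no quantitative
per-class lesion description exists to import. The default field is
64×64 pixels (a deliberate desk-scale reduction of the 512×512 clinical
resolution; size is a config knob, and the architecture reaches the full
setting by configuration). Images round-trip to disk as 8-bit grayscale
PNGs with a CSV manifest; the quantization error bound $1/255$ is asserted
in tests.

For 16×16 experiments the package uses a *lesion-crop* variant of the
generator configuration (gland band fraction 0.55, lesion radius fraction
0.20–0.28): at 16 pixels the default whole-field geometry leaves the
lesion ~2 px wide and the class signal is dominated by speckle, whereas
real small-field studies work with lesion-centered crops (the cropped
reader study is the clinical analogue). The choice was fixed after
measuring *classifier* accuracy on real phantoms only — the intrinsic
class separability of the rendering — not against any generative result.

What the phantom does **not** emulate: acoustic wave propagation,
vendor-specific post-processing, anatomical variability beyond the
banded-tissue abstraction, Doppler/cine modes. Passing tests therefore
demonstrate that the pipeline's machinery is correct and that its
statistical behavior matches theory on a controllable image family — not
that the model reaches clinical image quality.

# Evaluation methodology

**Inception Score.** $\exp\!\big(\mathbb E_x\, D_{KL}(p(y|x)\,\|\,p(y))\big)$
over the class-probability rows of a classifier; $0\log 0 = 0$; bounded by
$[1, K]$. Computed on the full set by default (split averaging is a
config knob).

**Fréchet distance.** $\lVert\mu_X-\mu_Y\rVert^2 +
\mathrm{tr}\big(\Sigma_X+\Sigma_Y-2(\Sigma_X\Sigma_Y)^{1/2}\big)$ with
unbiased covariance estimates; the matrix square root is taken on the
symmetrized product $\Sigma_X^{1/2}\Sigma_Y\Sigma_X^{1/2}$, clipping
eigenvalues in $[-10^{-6}, 0)$ and failing beyond that tolerance.

Both metrics run over a pluggable encoder interface. The desk-scale
default encoder is the penultimate (globally pooled) layer of the
phantom-trained classifier; a pretrained natural-image network could be
plugged in unchanged. Metric values are encoder-tagged and never compared
across encoders — with a domain-trained small encoder they are not on the
scale of published natural-image-encoder values, which is also why the
package does not claim to reproduce any published IS/FID figure.

**Privacy audit.** For a seeded subset of synthetic images (default 500),
cosine similarity in feature space against the full training set; rank-1..k
neighbors per image; pairs at or above a similarity threshold (default
0.98) are flagged. The clinical procedure uses human visual review rather
than a cutoff, so the numeric threshold is an automation artifact: the
report always carries the full candidate list for review, and an optional
exact 8-bit pixel-hash duplicate check provides a zero-false-negative
backstop. Exactness of the neighbor search is tested against an
exhaustive double loop, and planted duplicates must always be flagged.

**Reader-study statistics.** Fleiss' kappa from fixed-rater count
matrices with the six-band verbal scale (bands closed on the lower edge:
0.81 is "almost perfect"); Mann–Whitney AUC with tie correction and DeLong
confidence intervals; the DeLong paired test for correlated AUCs;
an exact, tie-aware Wilcoxon signed-rank test (dynamic programming over
doubled mid-ranks for $n \le 25$, tie-corrected normal approximation with
continuity correction above); and Wilson score intervals **with**
continuity correction for proportions. The Wilson-with-correction choice
was identified by matching independently printed confidence bounds of
published reader-study tables to one decimal; binary reader decisions are
treated as scores in $\{0,1\}$, which makes AUC $=$ (sensitivity +
specificity)/2 — also consistent with those tables. Where a published
experiment's raw data are not available, `confusionFromRates()`
reconstructs the binary outcome sets from printed sensitivity/specificity
and class sizes so the derived statistics can be recomputed and checked.

**Augmentation benchmark.** The utility experiment trains a binary
classifier (class 0 versus all higher classes pooled — the "biopsy
recommended" analogue) on an all-real training set versus a half-real/
half-synthetic set of the same size and class composition, evaluates every
fold model on one fixed external real test set under stratified 5-fold
cross-validation, and compares the per-fold AUC / sensitivity /
specificity / F1 with exact paired Wilcoxon tests. Sensitivity and
specificity use the 0.5 probability threshold (no threshold is published
for the reference experiment). With 5 folds the smallest achievable
two-sided exact p is $2/32 = 0.0625$, so "no significant difference" is
the expected outcome under equivalence.

The desk-scale classifier is a residual bottleneck CNN rather than a
50-layer network: a stride-4 patch-convolution stem (mirroring the
stem + pooling entry of deep residual nets), stages of 1×1-convolution
bottleneck residual blocks with 2×2 patch-convolution downsampling,
global average pooling, and a softmax head; widths (16, 32, 64) by
default, AdamW, cross-entropy, 50 epochs × batch 32 × learning rate
$10^{-4}$ as the reference protocol defaults. For 64×64 phantom
classification the package trains on 2×2 mean-pooled inputs with a
stride-2 stem: averaging 4 speckle draws per pixel raises the effective
SNR and lifts held-out 5-class accuracy above the 90% separability bar.
The pooled penultimate features double as the metric/audit encoder.

# Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; datasets are pure
  functions of their configuration, training runs of (data, config, seed).
* Forward/backward passes of all three networks are hand-derived on BLAS
  matrix primitives; correctness is enforced by finite-difference gradient
  checks in the test suite rather than by construction.
* GELU uses the tanh approximation; layer norm carries no learnable
  affine (adaLN provides scale/shift); Adam uses bias correction and
  decoupled weight decay.
* The EMA default decay 0.9999 matches the reference recipe, whose
  horizon (~$10^4$ steps) presumes long training; desk-scale runs of
  ~1500 steps use 0.995 so the EMA horizon matches the run length. This
  was fixed from the decay arithmetic, not tuned on outcomes.
* DDIM subsequences are uniform over $[1, T]$ and always contain $T$;
  $\bar\alpha_0 \equiv 1$ so the final step lands on the clean latent.
* Degenerate inputs fail loudly: empty datasets, shape mismatches,
  out-of-range timesteps/labels, non-finite losses (with the last finite
  loss reported), manifest/file/label errors on I/O.

## Desk-scale problem sizes

The package's own experiments (test suite and acceptance script) use:
5-class 64×64 phantoms, 200/class for classifier training; 500 phantoms
for VAE training (patch factor 2, width 16, 10 epochs); the 2-class 16×16
lesion-crop configuration for the end-to-end diffusion study (200/class,
denoiser depth 2 / hidden 64 / 2 heads / MLP ratio 2, 1500 AdamW steps at
batch 32 and learning rate $10^{-3}$, EMA 0.995; sampling $S = 50$,
$\omega = 0.8$); an independent judge classifier (300/class) for
conditional recovery; and a 200-image training pool with a 100-image
external test set for the augmentation benchmark (10 epochs per fold
model). These sizes are the package's choices for a single-CPU,
pure-R setting; every one of them is a config knob, and the full-scale
setting (512×512, factor-8 VAE, DiT-S, $S = 250$) is reachable by
configuration alone.

# Known limitations

* The phantom's five-feature morphology is a low-dimensional abstraction;
  distributional metrics computed on it say nothing about clinical realism.
* The covariance channels are architectural passengers under the default
  objective (DDIM $\eta = 0$ never reads them); they exist so the head
  matches the reference output contract and to support the optional
  variational-bound training.
* Pure-R training is orders of magnitude slower than framework-based
  training; the package is a correct, fully-inspectable reference
  implementation, not a performance tool.
* The exact Wilcoxon p at 5 folds cannot fall below 0.0625; equivalence
  claims from 5-fold comparisons are correspondingly weak, which is a
  property of the reference design, not of this implementation.
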