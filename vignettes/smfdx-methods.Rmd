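---
title: "Serum metabolic fingerprint diagnostics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum metabolic fingerprint diagnostics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfdx)
```

## The problem

A serum metabolic fingerprint (SMF) is the vector of metabolite ion
intensities measured from a droplet of serum by laser
desorption/ionization mass spectrometry, binned onto a fixed
mass-to-charge (m/z) grid. Fingerprints are cheap and fast to acquire,
which makes them attractive for disease screening — the setting this
package targets is a binary case/control classification (for example
stroke patients against healthy controls), with a handful of routine
clinical indexes (γ-glutamyl transferase, albumin, albumin/globulin
ratio, ...) available alongside each spectrum.

The package provides the full analysis chain:

1. **Fingerprint extraction** — peak lists binned onto a uniform grid
   (default 881 bins over 100–1000 Da), total-ion-current (TIC)
   normalization, cosine reproducibility scores.
2. **Classifiers** — a locally connected 1D neural network for
   fingerprints (here called the fingerprint network, exposed as
   `train_classifier()`), its multi-modal variant that fuses clinical
   indexes into the fully connected stage, and four classical baselines
   (LASSO logistic regression, random forest, SVM, and a from-scratch
   OPLS-DA).
3. **Evaluation** — ROC/AUC with DeLong confidence intervals and paired
   DeLong tests, Youden-index thresholds fixed on the discovery cohort,
   stratified k-fold cross-validation, label-permutation tests, and a
   normal-approximation power analysis.
4. **Interpretation** — gradient saliency maps aggregated over the
   discovery cohort, selection of a top-k metabolite feature panel with
   regulation directions, and a panel-restricted refit.
5. **Synthetic cohorts** — a generator with planted discriminative
   structure so that every stage is testable without patient data.

## The synthetic cohort generator

No public fingerprint cohort accompanies this problem, so the generator
*is* the study system. It emulates:

- **Baseline intensities**: independent log-normal per bin
  (`baseline_log_mean = log(100)`, `baseline_log_sd = 1`). Log-normal
  intensities with a coefficient of variation around 1.3 are what
  label-free single-shot MS intensities typically look like; the value is
  a package choice, fixed once.
- **TIC variation**: an optional shared log-normal per-sample scale
  factor (`sample_scale_log_sd = 0.3`), emulating shot-to-shot ion-current
  drift. This is what makes TIC normalization a non-trivial step.
- **Planted effects**: a configurable set of bins shifted in cases by
  `± log(effect_size)` on the log scale — multiplicative regulation, the
  way up/down-regulation of a metabolite is usually described. The default
  panel is 20 bins at 2-fold effect, half up and half down, spread evenly
  over the grid.
- **Clinical indexes**: normal per group with configurable means/sds and
  values deleted completely at random (default 5%). Default indexes use
  realistic units (γ-glutamyl transferase ≈ 28 vs 36 U/L, albumin ≈ 45 vs
  43.5 g/L, A/G ratio ≈ 1.55 vs 1.45).
- **Cohort shape**: 172 controls / 172 cases, split 4:1 into discovery
  (n = 275, 137/138 per class) and validation (n = 69, 35/34) by a
  stratified largest-remainder allocation.

What it does **not** emulate: peak shapes and profile-mode spectra,
isotope envelopes, correlated metabolite modules, batch effects, m/z
calibration drift, or instrument saturation. Tests passing on this
generator therefore demonstrate that the algorithms are implemented
correctly and can recover planted multiplicative structure at realistic
noise levels — not that any particular clinical performance would be
attained on real serum.

All randomness flows from one integer seed per cohort; the pipeline
derives per-stage seeds from a single master seed with a small
deterministic hash (`derive_seed()`), so any stage can be reproduced in
isolation.

## The fingerprint grid

The grid is a uniform partition of [100, 1000] Da into 881 half-open
bins `[lo, hi)` (the last bin closed), width ≈ 1.0215 Da. Peaks are
summed within a bin — summing conserves total ion current, which a
maximum would not. Peaks outside the range are dropped but tallied, so
`sum(binned) + dropped = sum(raw)` always holds. TIC normalization
divides each fingerprint by its total, and the cosine similarity of two
fingerprints is the usual inner product over the product of norms —
scale-invariant, hence unaffected by TIC normalization.

## The classifier

The fingerprint network stacks:

- **Four locally connected 1D blocks** (default kernels of width 9,
  stride 3, with 8, 8, 16, 16 channels; rectifier activations). A locally
  connected layer is convolution-like, but each spatial window owns its
  own weights — nothing is shared across positions. That matches the
  physics: the feature at 150 Da has nothing to do with the feature at
  850 Da, so translation invariance would be the wrong prior. Internally
  each block is one sparse-matrix multiply with a banded pattern;
  backpropagation accumulates weight gradients per window.
- **A nonlinear feature-interaction stage**: fully connected rectified
  layers (default 64 and 16 units) with dropout 0.3 after each, modelling
  dependencies among the extracted features.
- **A softmax classification layer** (2 units). The case-class softmax
  probability is the score used for all downstream ROC work.

For the multi-modal variant the clinical vector (median-imputed and
z-scored with discovery statistics) is concatenated with the input of a
feature-interaction layer. The default fusion point is the **last**
interaction layer: a 3-column clinical vector concatenated onto the
112-dimensional flattened spectral block gets diluted, and measurably
contributes nothing; at the 16-unit layer the two modalities meet at
comparable width, and the fused model reliably improves on the
fingerprint-only one when the clinical table carries independent signal.
`fusion_point = 1` restores fusion at the first layer.

### Input representation

Intensities are log-transformed (`log(x + 1e-12)`) and then z-scored per
bin with training-set statistics. Both choices matter in practice:
metabolite intensities are approximately log-normal, and training the
network on raw (heavily right-skewed) intensities leaves gradient
updates dominated by outliers — in our experiments validation AUC stayed
near chance without the log. The transform is stored in the model and
can be disabled (`transform = "none"`) for inputs that are not raw
intensities, e.g. the clinical-only multilayer perceptron.

### Regularization against the small-n / large-p regime

With ~137k parameters against ~275 training fingerprints of 881 mostly
uninformative bins, the raw network memorizes the training set within a
few epochs while learning nothing transferable. Three standard measures
are on by default and were chosen by measuring validation AUC on planted
synthetic cohorts:

- **input dropout 0.5** — randomly silencing half the input bins per
  step forces the extractor to accumulate evidence across many bins
  instead of memorizing individual noise bins; this single measure moves
  validation AUC from ≈ 0.5 to ≈ 0.85;
- **L2 weight decay 1e-3** on all weight matrices (not biases);
- **interaction-stage dropout 0.3**.

Dropout and learning rate (2e-3) were tuned on planted cohorts for joint
validation accuracy and saliency recovery of the planted bins; heavier
interaction-stage dropout (0.5) traded a little of both away.

### Training

Mini-batch Adam (learning rate 2e-3, batch 32), cross-entropy loss, an
80-epoch cap. Early stopping is implemented exactly as configured —
stratified holdout monitor, patience on monitored cross-entropy,
best-weight restore — but is **off by default** (`holdout_fraction = 0`):
at a few hundred samples, surrendering 10% of them to the monitor costs
more validation accuracy (≈ 0.05 AUC in our measurements) than stopping
early recovers, and with the regularized defaults the fit does not
degrade before the cap. When the monitor is enabled, a burn-in
(`early_stop_burn_in = 40`) keeps the noisy early loss curve from
halting training or capturing snapshots prematurely; a step
learning-rate schedule is available but disabled by default
(`lr_decay_factor = 1`).

All randomness (initialization, batch order, dropout masks, monitor
split) is seeded from `train_config(seed = )`; identical seed and inputs
reproduce identical fitted weights bitwise.

## OPLS-DA

Orthogonal partial least squares discriminant analysis is implemented
from scratch: predictors are centered/scaled and labels encoded as a
centered ±1 response; the X-weight vector proportional to `X'y` is
extracted, and `n_orthogonal` response-orthogonal components (the part of
each X-loading orthogonal to the predictive weights) are deflated before
a single predictive component is fit. Orthogonal scores have exactly
zero sample correlation with the response by construction, and with
`n_orthogonal = 0` predictions coincide with single-component PLS1 to
numerical precision — both properties are pinned by tests. Out-of-sample
projection re-applies the stored scaling and strips the stored
orthogonal directions sequentially. The continuous predictive score is
fed to the ROC harness like every other model; `n_orthogonal` defaults
to 1 and can be chosen by stratified cross-validation
(`select_n_orthogonal()`).

## Evaluation statistics

- **AUC** is the Mann–Whitney concordance probability computed from
  midranks (ties count 1/2); it equals brute-force concordant-pair
  counting, which the tests verify exhaustively on small instances.
- **DeLong intervals and tests** use the placement-value (structural
  components) estimator; intervals are formed on the identity scale and
  clipped to [0, 1] (logit scale by flag). The paired test uses the
  covariance of placement values; two identical score vectors give
  p = 1 by definition. Both agree with the independent pROC
  implementation to 1e-8 in tests, and null simulations show ~95%
  coverage and approximately uniform p-values.
- **Youden threshold**: the cut maximizing sensitivity + specificity − 1
  over midpoints between adjacent unique scores (±∞ sentinels). Ties are
  broken toward the higher-specificity cut — in a screening context the
  cheaper error is a missed case follow-up, not a false alarm; the
  tie-break is documented and deterministic. A sample is called a case
  iff its score is strictly greater than the threshold. The threshold is
  fixed on discovery and applied unchanged to validation.
- **Cross-validation**: stratified k-fold with per-class round-robin
  dealing (staggered across classes so fold sizes differ by at most
  one); metrics are computed per fold and averaged, with pooled
  out-of-fold scoring by flag.
- **Permutation test**: `p = (1 + #{permuted ≥ observed}) / (B + 1)`,
  the add-one estimator — p is never zero and B = 999 gives a floor of
  exactly 0.001.
- **Power analysis**: the two-sided two-sample normal approximation
  `n/group = 2((z_{1−α/2} + z_{power})/d)²`, rounded up. The effect size
  d is a required input.

## Saliency-based feature selection

The saliency of input bin j for a sample is `|∂ logit_case / ∂ x_j|`,
the classical input-gradient saliency map, evaluated with dropout
disabled. Gradients are taken with respect to the network's own
standardized inputs, so saliencies are comparable across bins regardless
of raw intensity scale; for a pure linear scorer the map is exactly
`|w|`. Maps are averaged over **all** discovery samples (both classes;
per-class aggregation is a flag away), the top-k bins form the feature
panel (ties toward the lower bin index), and each selected bin's
regulation direction is called from discovery means on the
TIC-normalized scale (`up` if the case mean exceeds the control mean)
with the case/control ratio recorded as fold change.

Fingerprints can be reshaped to the smallest square grid
(`make_layout()`; 881 bins → 30 × 30 with 19 zero-padded cells) for
heat-map visualization, mirroring how image saliency is displayed. The
layout is visualization only: gradients are computed on the 1D network
inputs, so the layout cannot affect scores, and padded cells carry zero
saliency by construction.

`refit_on_panel()` retrains a fresh network restricted to the panel bins
and pushes it through the standard split harness, quantifying how much
discriminative signal the panel retains. For narrow inputs the default
locally connected stack shrinks its kernels (width 3, stride 1) so four
blocks still fit; below 5 bins it degrades to a multilayer perceptron.

## Numerical and design notes

- Binning uses `floor((mz − mz_min)/width)` with the last bin closed;
  peaks exactly on an interior edge belong to the upper bin.
- TIC normalization refuses all-zero fingerprints (an empty acquisition
  is an error, not a zero vector); cosine similarity refuses zero-norm
  inputs.
- Constant feature columns are dropped with a warning by OPLS-DA and
  given unit scale by the network's z-scoring (a zero column after
  standardization).
- Degenerate DeLong variance (perfect separation) yields a point
  interval plus warning rather than an error.
- The stratified split allocates validation slots to classes by largest
  remainder, so a 172/172 cohort at fraction 0.2 gives exactly 35/34
  validation and 137/138 discovery per class.
- Problem sizes in the test-suite: most statistical checks run at
  n ≤ a few hundred with hundreds of simulations; network properties are
  exercised on the full 881-bin, 344-sample study shape where the claim
  depends on it (signal recovery, permuted-label null, fusion benefit)
  and on reduced shapes everywhere else. These sizes are the package's
  own choices to keep the default check fast while preserving each
  claim's operative conditions.

## Known limitations

- The generator's independence across bins understates the collinearity
  of real metabolite panels; saliency recovery on real data will face
  correlated confounders that are absent here.
- The network is a CPU implementation in R; it is sized for hundreds of
  samples and ~1000 bins, not for profile-mode spectra or cohorts of
  thousands.
- mzML support covers centroided peak lists only (through mzR); no
  vendor formats, no peak picking, no recalibration.
- Binary classification only.
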