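---
title: "Classifying dream and dreamless sleep from EEG: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dream and dreamless sleep from EEG: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamsift)
```

## The problem

In serial-awakening sleep studies, subjects are repeatedly woken and asked
whether they were dreaming. Each report yields a short stretch of
immediately preceding multichannel EEG and a binary label: *dream* (the
minority class, roughly a quarter of reports) or *dreamless*. dreamsift
implements a complete pipeline for two questions:

1. Can dream and dreamless EEG segments be told apart automatically?
2. How few electrodes are needed, and which ones?

The second question matters because 58-channel research caps are
impractical outside the lab; a wearable device needs a handful of
well-chosen sites.

## Pipeline overview

Raw recordings pass through a fixed preprocessing chain — re-referencing to
the mastoid average $(A1 + A2)/2$, downsampling (200 Hz by default),
zero-phase band-pass filtering (0–35 Hz by default), and segmentation of
each report into non-overlapping fixed-length segments (2 s by default) —
and then into one of two feature paths:

* **CSP path.** Common spatial patterns: spatial filters $w$ solving the
  generalized eigenproblem $\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_0) w$
  on the two class covariance matrices, ordered by descending $\lambda$.
  Each segment is represented by the log-variance of every filtered
  component, rotated by PCA and z-scored.
* **DWT path.** A four-level discrete wavelet transform (biorthogonal 2.2)
  per channel gives five sub-bands; on each sub-band ten statistics are
  computed (four fractal dimensions, two log-energies, the two Hjorth
  descriptors, kurtosis, skewness), concatenated channel-major and
  z-scored. With 58 channels the vector has $58 \times 5 \times 10 = 2900$
  entries.

Either feature set feeds one of five classifiers (gradient boosting, RBF
SVM, k-nearest neighbors, ridge logistic regression, a one-hidden-layer
perceptron), evaluated with accuracy, F-score, precision, recall and AUROC
— the dream class is always the positive class, and F-score is the binary
(positive-class) variant. Channel subsets are then searched two ways:
permutation importance with top-k retraining, and a six-objective NSGA-II
over binary channel masks.

## The synthetic generator

Real polysomnography cannot ship with a package, so every stage is
exercised against a generator (`synth_config()`,
`generate_labeled_dataset()`) that reproduces the *statistical shape* the
pipeline assumes rather than sleep physiology:

* **Montage and rates.** 58 named 10–10 electrodes plus low-amplitude
  mastoids A1/A2, 400 Hz raw sampling, dream prior 0.23, and an
  awake-assumption flag on 34.3% of reports — the shape of the serial
  awakening datasets this pipeline targets. All are configurable.
* **Background.** Per channel and report: pink (1/f) noise plus
  delta/theta/alpha oscillations with random per-report frequency and
  phase, scaled by `noise_sd` (microvolts). This matches the 1/f-plus-peaks
  gross spectral shape of sleep EEG without modeling sleep microstructure.
* **Class effect.** Dream reports add an independent narrow-band sinusoid
  (default 8–12 Hz) on each *informative* channel, with amplitude
  `effect_size * noise_sd` jittered per report. The effect is additive
  band-limited power — deliberately the simplest structure that both a
  spatial-variance method (CSP) and a sub-band-energy method (DWT) can
  detect, so both paths are testable against the same plant.
* **Partial expression.** Each informative channel expresses the effect in
  a given dream report only with probability `effect_expression` (default
  0.85). Dream signatures in real data wax and wane across reports; the
  modeling consequence is that no single channel is sufficient for every
  report, so *combinations* of channels are genuinely more informative
  than any one of them. Without this, one strong channel saturates all
  five metrics and channel-subset search degenerates to picking any single
  planted channel.
* **Seeding.** One master seed; each subject's stream is derived by a
  fixed offset, so datasets are bit-reproducible and subjects independent.
* **Epoch length.** The duration of a report's EEG epoch is configurable
  with no fidelity claim (`epoch_len`, default 10 s). See "Leakage"
  below for why validation studies often set it equal to the segment
  length.

What the generator does **not** emulate: sleep-stage dynamics, artifacts
(blinks, EMG), volume conduction between electrodes, and any
physiologically accurate dream signature. Tests passing on this generator
show the *machinery* is correct — recovery of planted structure, null
calibration, train/test hygiene — not that real dream EEG is classifiable
at any particular accuracy.

## Numerical and design choices

* **Filter realization.** Zero-phase forward–backward Butterworth. The
  order default is 6: a forward–backward order-4 filter leaves a 50 Hz
  tone at about 2% of its input RMS inside a 0–35 Hz design band at
  200 Hz, while order 6 reaches 0.3%, comfortably within the stop-band
  contract (≤ 1%) documented for `bandpass_filter()`. The 0 Hz lower edge
  is implemented literally as a pure low-pass; no DC removal happens
  beyond mastoid re-referencing.
* **Resampling** is rational-rate polyphase (via the signal package), with
  output length `floor(n * target_fs / fs)`.
* **CSP conditioning.** Each segment covariance is normalized by its trace
  before class averaging (amplitude-outlier robustness); each class
  covariance is shrunk toward a scaled identity with weight 1e-6. Applying
  shrinkage per class (rather than to the composite) keeps the whitened
  two-class eigenvalue identity $\lambda_i^{(1)} + \lambda_i^{(0)} = 1$
  exact to machine precision, which the test suite asserts at 1e-8.
  Log-variance uses a 1e-12 floor so flat segments stay finite.
* **PCA as a rotation.** Both CSP components and PCA components default to
  the channel count, making PCA a pure rotation. Whether dimensionality
  should instead be truncated is left to `csp_components`; the default
  follows the component-count convention of the study design this package
  reimplements.
* **Wavelet conventions.** Filters are the exact dyadic-rational bior2.2
  taps times $\sqrt 2$; boundary handling is half-point symmetric
  extension; coefficient counts are `floor((n + 5) / 2)` per step. These
  conventions match the mainstream wavelet libraries so coefficient-level
  results are portable; reconstruction is exact to rounding (asserted at
  1e-8).
* **Feature definitions pinned.** Instantaneous energy
  $\log_2(\tfrac1n\sum x^2)$ and Teager energy
  $\log_2(\tfrac1{n-2}\sum |x_i^2 - x_{i-1}x_{i+1}|)$, both floored at
  1e-12; kurtosis is Fisher excess; Higuchi uses `kmax = 10` (a common EEG
  default that is stable on 400-sample segments; shorter sub-bands fall
  back to `length/2`). The "Sevcik" estimator follows Sevcik's
  normalized-polyline formulation. Feature order is channel-major,
  sub-bands from the level-4 approximation down to detail 1.
* **Classifier defaults.** Chosen once as conventional settings: GB =
  50 trees, depth 3, learning rate 0.3; SVM = RBF, cost 1, gamma $1/p$;
  KNN = 5 neighbors (with optional inner-CV selection up to 20, ties to
  the smaller k); LR = ridge-penalized logistic regression with a small
  fixed penalty (plain maximum likelihood is ill-posed when features
  outnumber rows, as with 2900 DWT features); MLP = 10 hidden units,
  weight decay 1e-3. Every stochastic learner is seeded through its spec.
* **Permutation importance.** One uniform random permutation per
  (fold, channel) by default, mirroring the single-draw description of the
  procedure; `permute_reps` raises the draw count for variance reduction
  when the null band matters. Ranking key is the mean delta across the
  five metrics, ties broken by accuracy delta then channel index.
* **NSGA-II.** Binary masks over channels; objectives
  $(\#\text{channels}, -\text{acc}, -F, -\text{prec}, -\text{rec},
  -\text{AUROC})$, all minimized. Uniform crossover (p = 0.9), per-gene
  bit-flip mutation (p = 1/C), binary tournament on (rank, crowding),
  elitist merge of parents and offspring, all-zero masks repaired to one
  random gene. Termination: every 10 generations the bounding box of the
  non-dominated set's objectives is compared with the previous check; a
  maximal normalized change below 0.001 stops the run, with a hard cap of
  200 generations. Every mask evaluation is a seeded stratified 70/30
  split, memoized by bit pattern so revisited masks cost nothing.

## Leakage, and the by-report grouping option

Consecutive segments cut from one report share the report's slowly varying
amplitude and spectral character. With plain stratified splitting, sibling
segments of one report land on both sides of the split, and
instance-memorizing learners (KNN above all) recognize them, inflating
every metric — on strongly planted synthetic data a single good channel
then scores a perfect 1.0. `make_cv_splits(grouping = "by-report")` keeps
each report on one side and removes this optimism; the default remains
ungrouped splitting, which is the convention of the study design this
package follows. The package's own validation experiments sidestep the
issue a second way: generator configurations for subset-recovery checks
use reports exactly one segment long, so there are no siblings to leak.

## Problem sizes used by the test suite

The suite exercises full pipelines at deliberately compact sizes, chosen
as the smallest at which the statistical claims are stable: generation at
100 Hz; 58-channel datasets of about 600 2-s segments for channel-ranking
checks; 16-channel montages (about 400–1000 segments) for Pareto-search,
null-calibration and chance-band checks; an 8-channel montage where the
true Pareto front is computed by exhaustive enumeration of all 255 masks.
Planted effects use `effect_size = 3` — strong enough that recovery
failures indicate bugs rather than noise — and recovery claims are
averaged over 5–10 generator seeds.

## Known limitations

* Synthetic validation only: no claim transfers to real sleep EEG beyond
  the correctness of the machinery.
* The DWT path is computationally heavy in plain R (2900 features per
  segment at 58 channels); the evaluation loops precompute the feature
  matrix once per dataset, but large DWT grids remain slow.
* KNN's AUROC rests on vote fractions, a coarse score with many ties.
* The NSGA-II termination test is one concrete reading of an
  "objective-space tolerance"; other readings (e.g., sliding-window
  point-set distances) would stop at different generations.
* Single-split chromosome evaluation makes the Pareto front an estimate
  under one split's sampling noise; `run_nsga()` exposes the split seed so
  sensitivity can be checked.
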