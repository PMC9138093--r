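---
title: "Methods: simulated EEG preference recognition and feature selection"
author: "eegpref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated EEG preference recognition and feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegpref)
```

This vignette documents the models, parameter choices and numerical
conventions behind `eegpref`, and what the package's validation suite
does and does not establish.

## The generative model

`make_dataset()` simulates a like/dislike neuromarketing panel: by
default 25 subjects contribute 42 trials each (1,050 epochs), recorded
on the 14-channel Emotiv-style 10–20 montage at 128 Hz. Each epoch lasts
4 s (512 samples); that length is chosen so a full-epoch 512-point FFT
gives a 257-bin one-sided spectrum with no padding, keeping the time and
frequency dimensions of the extracted features in a fixed, documented
relationship.

Per channel the signal is a sum of band-limited oscillations plus pink
noise:

* per band (theta 4–8, alpha 8–12, beta 12–30, gamma 30–45 Hz), three
  sinusoids with frequencies drawn uniformly in the band and phases
  uniform on $[0, 2\pi)$. Three oscillators per band is the smallest
  number that avoids a line spectrum while keeping the band envelope
  irregular across epochs; the upper gamma edge is 45 Hz because the
  emulated acquisition applies a 4–45 Hz bandpass.
* additive $1/f$ (pink) noise, generated by spectrally reshaping white
  Gaussian noise, rescaled to a target standard deviation.

Default amplitudes (theta 4, alpha 6, beta 3, gamma 1.5, pink noise SD
5, in arbitrary microvolt-like units) follow the usual resting-EEG
ordering — alpha dominant, gamma weakest, broadband noise comparable to
the strongest rhythm. Between-subject variability is a multiplicative
log-normal jitter on the band amplitudes (SD 0.2 on the log scale),
drawn from a stream keyed on (seed, subject), so a subject keeps one
amplitude profile across trials and subject-pooled splits contain
genuine subject structure.

The class signal is a single effect-size parameter $\delta \in [0, 1)$:
for a "like" trial, alpha amplitude at the left frontal electrodes
(AF3, F3) is scaled by $1-\delta$ and at the right (AF4, F4) by
$1+\delta$, with the mirror-image scaling on beta; "dislike" reverses
both. This is the textbook frontal-asymmetry signature: relatively lower
left-frontal alpha for approach states, and it makes the
approach/withdrawal and valence indices positive in expectation for
"like". Non-frontal channels never carry class information, so any
classifier signal found there would indicate a bug, not a discovery. At
$\delta = 0$ the two classes are draws from the same distribution — the
null-calibration tests depend on this exactly.

Per-subject like rates are drawn from a Beta(5, 5) clipped to
[0.2, 0.8]: preferences plausibly vary by subject but neither class
disappears. The whole dataset is a pure function of the configuration,
including its seed.

The default $\delta = 0.5$ is a strong effect — the valence and AW
indices separate the classes with rank AUC near 1. The generator is
meant to verify recovery machinery, not to calibrate realistic effect
sizes; real preference EEG has far lower signal-to-noise, plus
artifacts (blinks, EMG), non-stationarity and sensor noise that the
model deliberately omits. Passing tests therefore demonstrate
correctness of the pipeline, not expected field performance.

## Spectral conventions

* **PSD**: full-epoch one-sided periodogram, `nfft = 512`, no Welch
  averaging or tapering — forced by the fixed 257-bin feature dimension.
  Normalisation is Parseval-consistent: summed bins × bin width equal
  the mean squared signal (verified to 1% on random epochs).
* **Band power**: the *mean* PSD over bins in the half-open interval
  `[low, high)`; the gamma ceiling (45 Hz) is inclusive since it is the
  bandpass edge. Powers are floored at $10^{-12}$ so the logarithmic
  indices are always defined; the indices themselves never floor.
* **Morlet block**: 61 linearly spaced centre frequencies over 4–45 Hz,
  7-cycle complex Morlet, unit-energy kernel, FFT circular convolution;
  the feature is the time-averaged squared magnitude. Width 7 is the
  common compromise between time and frequency resolution at these
  frequencies.
* **Spectrogram block**: 128-sample Hann windows at 50% overlap (7
  frames per epoch), time-averaged power per frequency row (65 rows),
  with the same PSD normalisation plus the window energy correction, so
  rows are comparable to a 128-point periodogram.
* The assembled vector concatenates per-channel PSD (4 × 257),
  cross-channel sum and average (2 × 257), Morlet (4 × 61), spectrogram
  (4 × 65) and the ten indices: 2,056 named features. Features are keyed
  by name throughout; permuting input channels never changes a named
  value.

## The preference indices

The ten indices are ratio, difference and log-difference contrasts of
frontal band powers (see the README for the formulas). Where an index
takes a two-electrode argument such as `alpha(AF4, F4)` the package uses
the *arithmetic mean* of the two electrodes' powers. The combination
rule is a genuine design choice (sum would also be defensible); the mean
keeps pair-based and single-electrode indices on the same scale and
leaves the log-difference valence index identical up to the constant
that a sum would add. The choice indices use the natural logarithm; by
their ratio structure any log base gives the same value, which the test
suite asserts directly.

Two algebraic facts are worth stating because the tests rely on them:
the eight asymmetry contrasts are antisymmetric under a left/right
electrode swap, and the normalised ratio indices are bounded in
$[-1, 1]$ *provided* numerator and denominator logs share a sign. When a
band power crosses 1, the log changes sign and a choice-index
denominator can pass through zero; the index is then unbounded and
unstable. The package returns the computed value but warns when the
denominator is within $10^{-9}$ of zero, leaving the handling policy to
the caller. The bounded-range property tests sample powers bounded away
from 1 for exactly this reason.

## Feature selection

* **Mutual information** uses equal-frequency discretisation (3 bins,
  type-7 quantiles) and the plug-in estimator in bits. Three bins is
  coarse but stable for tables of roughly a thousand rows; inputs with
  at most three distinct values keep their natural levels, so a binary
  feature against a binary label attains its exact entropy bound.
* **mRMR** is greedy forward selection; the default scheme is the
  quotient (relevance / mean redundancy), with the difference scheme
  also available. Pairwise feature MI is cached; ties break on the
  ascending original feature index, making selection deterministic. On
  small tables the implementation is tested to coincide with an
  exhaustive re-evaluation of the criterion at every step.
* **ReliefF** uses all instances, Manhattan distances on internally
  min-max-normalised features, 10 neighbours by default, and
  prior-weighted misses. Weights land in $[-1, 1]$; constant features
  get exactly 0. The operation refuses classes with fewer than
  `n_neighbors + 1` members; the pipeline caps the neighbour count at
  the smallest class size minus one rather than failing on small runs.
* **RF-RFE** eliminates the lowest 10% (by Gini importance) per
  iteration down to 10 survivors by default. The step size is a free
  parameter of the procedure; 10% trades runtime against the risk of
  discarding a feature whose importance is masked by correlated
  partners. Importances are normalised to sum to one, and rows are
  canonically sorted before each forest fit so that importances are
  deterministic given a seed and invariant to row order.
* **PCA** is used as an unsupervised transformer (components, not
  original names, feed the classifiers), mean-centred without scaling,
  with a fixed sign convention (largest-magnitude loading positive).
  The component count is a required choice; the benchmark default is 1,
  treating the leading variance direction as the single unsupervised
  summary, but any count can be configured.

## Classification protocol

The holdout split is stratified (per class, `round(0.2 n)` test rows, at
least one), with a subject-grouped option for panels where trials within
a subject are not exchangeable. Features are z-scored with training-fold
statistics for all classifiers except the random forest, which is
invariant to monotone feature scaling. Classifier defaults: 1-NN,
500-tree forest, LDA with its single discriminant (binary problem), SVM
with the radial kernel at library defaults, and a hinge-loss MLP.

The MLP is specified only by its loss in the protocol this package
follows, so its architecture is a package choice: two hidden layers
(64, 32) of rectified units, a linear output, full-batch Adam (learning
rate 0.01), at most 200 epochs with early stopping on a training-loss
plateau, and seed-controlled initialisation. It is intentionally small:
large enough to fit a nonlinear boundary on selected features,
deterministic and fast enough for repeated benchmark runs.

Metrics are computed from the 2×2 confusion matrix with class-frequency
weighting, under which weighted recall equals accuracy; the F-measure is
the harmonic mean of the aggregated precision and recall.

**Leakage policy.** By default every selector (and PCA, and the z-score
statistics) is fitted on the training fold only and applied to both
folds. A `legacy_mode` fits selectors on the full table before the
split — some published pipelines are ambiguous on this point, and the
mode allows quantifying how much optimism that introduces. The test
suite plants a canary feature equal to the label only on test rows:
under the default mode it must not (and does not) lift test accuracy,
while legacy-mode selection picks it up immediately.

## Reproducibility and problem sizes

Every stochastic component (generator, splits, forests, MLP
initialisation) is seeded, and the pipeline derives stage seeds from one
master seed; reruns are byte-identical. The validation suite uses the
full 25 × 42 design for the structural checks (epoch count, RFE on a
1,050 × 300 table, selector recovery among 200 noise features) and
smaller panels (6 subjects × 20 trials, index features) for the
ten-seed null calibration, where the quantity of interest — mean holdout
accuracy against its binomial standard error — does not require large
single datasets. The acceptance script mirrors these sizes.

## Known limitations

* The oscillator-plus-pink-noise model has no artifacts, no 1/f slope
  variation, no band-power covariance structure beyond the planted
  asymmetry, and stationary epochs; results on it bound correctness,
  not field accuracy.
* The plug-in MI estimator with 3 bins underestimates MI for strongly
  nonlinear dependencies; it is used for ranking, where only the order
  matters.
* ReliefF is $O(n^2 p)$ in time and $O(n^2)$ in memory from its distance
  matrix; for panels much larger than this design, instance sampling
  (not implemented) would be the standard remedy.
* 1-NN ties and SVM numerical paths are deterministic on the tested
  platforms but, unlike the seeded components, carry no explicit
  tie-break guarantee.
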