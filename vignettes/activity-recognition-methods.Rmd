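---
title: "Methods: recognising weight-bearing activity from hip-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognising weight-bearing activity from hip-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`accelgait` classifies short segments of raw hip-worn triaxial
accelerometer signal into weight-bearing activity types — standing,
walking and jogging — the activities most relevant to skeletal loading
in populations at risk of osteoporosis. The design target is
incremental shuttle-test data from postmenopausal women: an instrumented
protocol in which a participant stands for three minutes and then walks,
and eventually jogs, at speeds that increase every 90 seconds, on either
a 20 m indoor track or a treadmill. This vignette documents the model
assumptions, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The pipeline

1. **Acquisition / simulation.** Raw triaxial acceleration in g at 50 Hz
   (a minority of devices record at 100 Hz), axes x = anterior/posterior,
   y = vertical, z = medial/lateral, annotated per sample with the
   protocol stage.
2. **Preprocessing.** 100 Hz recordings are decimated to 50 Hz after an
   anti-alias low-pass at 0.8 x the target Nyquist; the gravity band
   (0–0.8 Hz, dominated by the +1 g offset on the vertical axis) is
   removed with a Hamming-window FIR high-pass, cut-off 0.5 Hz, order
   1000.
3. **Windowing.** 2-second windows (100 samples at 50 Hz) with 50%
   overlap; windows that straddle a stage boundary are dropped so every
   window has an unambiguous label.
4. **Features.** 18 features per axis, 54 per window: mean, median,
   standard deviation, 25th/75th percentiles, skewness, kurtosis,
   principal frequency, spectral energy, Lempel–Ziv complexity, central
   tendency measure, correlation dimension, and six Daubechies-2 wavelet
   band energies.
5. **Feature sets.** Nine constructions: all features (A), a
   3-component PCA reduction (B), NCA-selected subsets with default and
   zero regularisation (C1, C2), NCA followed by PCA (D), basic
   statistics (E), frequency domain (F), nonlinear (G) and wavelets (H).
6. **Classifiers.** k-NN with Manhattan or Euclidean distance (k = 10),
   a CART decision tree, and a linear soft-margin SVM (one-vs-one for
   three classes).
7. **Validation.** A random 70/30 split for screening, 10-fold
   cross-validation for the sets carried forward, and leave-one-source-out
   (LOSO) — hold out all windows of one recording per fold — as the
   honest repeatability estimate.

Two labelling schemes coexist. The binary task is protocol-wide: stage 1
is Standing and stages 2–8 are Walking, regardless of what an individual
was actually doing, so only stage 1–8 windows enter it. The tertiary
task is per-recording: each subject has a jog-onset stage (stage 7 or
later), and every stage from it onward is Jogging.

## The synthetic cohort generator

The original study's recordings are not publicly archived, so the
package ships a generator that emulates the statistical structure the
pipeline exploits, and every empirical claim in this package is made
about this synthetic cohort, not about human data. Defaults reproduce
the study conditions: 80 track + 30 treadmill recordings (the
participant count the protocol reports; the number of treadmill tests is
configurable), 39 of 110 recordings at 100 Hz, stage speeds 0, 2.4, 3.0,
3.6, 4.3, 4.9, 5.5, 6.1, 6.7, 7.3, 7.9, 8.5, 9.1, 9.8, 10.4 km/h, 180 s
for stage 1 and 90 s for the rest.

The gait signal model is deliberately simple: each moving axis is a sum
of three harmonics of a subject-specific step frequency plus Gaussian
sensor noise, the vertical axis carries a +1 g gravity offset, and
standing is sway (two tones below 0.8 Hz) plus noise. Parameters are
drawn per subject:

* **Step frequency**, linear in speed. Walking:
  intercept ~ N(1.35, 0.08) Hz, slope ~ N(0.107, 0.012) Hz/(km/h), which
  spans roughly 1.6–2.2 Hz over the walking speeds; jogging:
  intercept ~ N(1.55, 0.10), slope ~ N(0.14, 0.015), roughly 2.4–3.0 Hz.
  These ranges follow the adult gait literature; the subject-level
  jitter makes the walking and jogging distributions adjacent, so
  windows near the jog onset are genuinely confusable across subjects —
  without it, classification would be unrealistically easy.
* **Vertical amplitude**: 0.075 ± 0.012 g per km/h (truncated at 0.04),
  with a discontinuous multiplicative jump at jog onset drawn log-normal
  around 1.6 (truncated at 1.2). The truncation guarantees that within
  any one recording jogging windows have strictly larger vertical SD
  than walking windows, while the between-subject spread creates
  walk/jog overlap across subjects.
* **Axis amplitude ratios** 0.45 (anterior/posterior) and 0.25
  (medial/lateral), harmonic weights 1 : 0.4 : 0.2.
* **Noise** SD 0.03 ± 0.005 g; **sway** amplitude 0.02 ± 0.005 g.
* **Jog onset** uniform on stages 7–9; **final stage** drawn on 8–15
  with probabilities (.10, .15, .20, .20, .15, .10, .06, .04), so only a
  few percent of subjects finish the whole test — the completers carry
  the fastest, most confusable windows, mirroring the protocol's
  observation that the high-speed stages are the hard ones.
* **Track vs treadmill**: track recordings get a medial/lateral burst
  every 20 m of simulated distance (the shuttle turns); treadmill
  recordings do not.

Reproducibility: one master seed; each recording derives an independent
substream seed from a stable polynomial hash of its source id, so
cohorts are bit-identical across runs and individual recordings can be
regenerated in isolation.

**What the generator does not emulate:** device quantisation and
idle-sleep, soft-tissue and footwear transients, asymmetric gait,
accelerometer saturation, within-stage speed drift, and the
walk/run mixing some participants use at intermediate speeds. Passing
tests on this cohort therefore demonstrate that the pipeline recovers
class structure of the kind the protocol produces — amplitude and
frequency discontinuities at activity transitions — not that it attains
any particular accuracy on human recordings.

## Numerical choices

* **FIR group delay.** The order-1000 filter has a 10 s group delay at
  50 Hz. Labels are time-aligned with the signal, so the filter is
  applied with exact delay compensation and one filter length (500
  samples per end) trimmed; stage annotations are trimmed in lockstep.
* **Filtering precedes windowing** (the alternative order would leave
  each window's filter transient inside the window).
* **Median and percentiles**: sample median (mean of central order
  statistics for even n); percentiles by linear interpolation of order
  statistics (type 7).
* **Skewness/kurtosis** are the standardised central moments
  m3/m2^1.5 and m4/m2^2; a constant window has no defined moments and is
  flagged invalid.
* **Principal frequency** excludes the DC bin (meaningless after the
  high-pass) and breaks ties toward the lower frequency; spectral energy
  is the unnormalised sum of squared FFT magnitudes over all bins.
* **Lempel–Ziv complexity**: binarise at the window median (values at
  the median count as 1), parse with the 1976 exhaustive-history
  algorithm, normalise by c(n) log2(n)/n. The asymptotic value for
  random strings is 1, but at n = 100 the finite-size excess is large:
  balanced random strings score about 1.0–1.4, so downstream code treats
  the value as a bounded score on [0, 1.4], not a probability.
* **CTM** uses radius 0.1 g and denominator N − 2, strict inequality.
* **Correlation dimension** (Grassberger–Procaccia): embedding dimension
  5, delay 1 sample, 20 log-spaced radii between the 5th and 95th
  percentile of pairwise embedded distances; the estimate is the
  least-squares slope of log C(r) vs log r over the widest contiguous
  radius run (at least 5 radii) whose local slopes stay within 0.2 of
  their mean. Windows with no valid scaling region (near-constant
  signal, too few distinct distances) fail; failure marks the window
  invalid for the feature sets that include identifiers 10–12, which is
  why those sets have fewer data points than the others. A 2-s window is
  far below the data requirement for a defensible dimension estimate —
  the value is used as a discriminative feature, not as an estimate of
  attractor dimension.
* **DWT**: Daubechies-2, three levels, periodized (circular) filter
  bank. 100 → 50 → 25 leaves an odd length at level 3; the odd-length
  approximation is zero-padded by one sample before the next level, so
  the transform stays exactly orthogonal with respect to the padded
  signal and coefficient energy equals signal energy to machine
  precision. The six features are the band energies (details at levels
  1–3 and approximations at levels 1–3); energy was chosen over, e.g.,
  the coefficient SD for this conservation property.
* **Standardization.** Features span orders of magnitude (g vs squared
  FFT energy), so every feature set is z-scored with training-fold
  statistics before distance-based models, NCA and PCA; constant columns
  get unit scale. PCA therefore operates on the correlation scale.
* **NCA** learns non-negative per-feature weights by stochastic
  gradient ascent (50 epochs, step 0.05, weights projected to be
  non-negative) on the soft-nearest-neighbour leave-one-out objective,
  with weighted Manhattan distances and a self-normalising kernel width
  (per reference sample, the mean weighted distance at the current
  weights, so neighbour probabilities stay spread as weights move);
  regularisation is 1/n for C1 and 0 for C2, and
  features with weight strictly above 0.2 are kept. NCA cost is
  quadratic in rows, so fits use a seeded subsample of at most 1000
  training rows. NCA (and every other transform) is refitted inside
  every fold; whether the original analysis refitted per fold is
  unknown, and per-fold refitting is the leakage-free choice.
* **k-NN ties**: vote ties break by the smaller mean distance among the
  tied classes, then by class-name order; equal distances at the k-th
  neighbour keep the earlier training row.
* **CART**: Gini impurity, minimum leaf 5, no depth cap, no pruning.
* **SVM**: the kernel and cost are not prescribed anywhere, so the
  package defaults to the linear kernel the decision function implies
  with C = 1, one-vs-one for three classes; both are configurable.
* **Sampling unit.** The 70/30 and 10-fold protocols randomise windows,
  not subjects, so overlapping windows from one recording can appear on
  both sides of a split; these two protocols therefore overestimate
  generalisation, and LOSO is the estimate to trust. The package keeps
  the window-level protocols because the experiment design uses them for
  screening.

## Problem sizes and compute caps

The default cohort yields roughly 115k windows (about 88k in the binary
task), chosen to match the protocol durations rather than any runtime
target. The compiled k-NN searches the full training split in every
fold. Two models get seeded training-row caps in the large experiment
drivers: the SVM (10k rows; libsvm's fitting time is superquadratic, and
the experiment design itself drops the SVM from tertiary LOSO for
runtime) and, in the LOSO analysis script only, the decision tree (30k
rows per refit). k-NN and all reported headline results never
subsample. NCA's 1000-row fitting cap is described above.

## Known limitations

* Results on the synthetic cohort are upper bounds of a sort: the
  generator's class structure is exactly the kind the features measure.
  The per-class error ordering (jogging hardest, standing easiest)
  reproduces qualitatively, but absolute accuracies on human data will
  differ.
* The LZ normalisation can exceed 1 for short windows; downstream code
  treats it as a bounded score, not a probability.
* The correlation dimension fails on a nontrivial fraction of quiet
  windows by design; sets containing it silently operate on fewer
  windows, exactly as the experiment design's point counts do.
* `read_raw_csv` expects the package's own CSV dialect; adapting real
  ActiLife RAW exports requires a column mapping upstream.
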