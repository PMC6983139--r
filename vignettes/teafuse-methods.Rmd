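---
title: "Methods: feature fusion for cross-category tea polyphenol estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature fusion for cross-category tea polyphenol estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Problem and scope

Tea polyphenols (TP) are the dominant bioactive fraction of tea leaves
and a standard quality index, expressed here as a mass percentage.
Wet-chemistry determination (direct potassium-permanganate titration,
`titration_to_tp()`, with the conventional conversion factor
0.00582/0.318 kept symbolic as `tp_titration_factor`) is destructive
and slow; the package implements a nondestructive alternative that
fuses two sensing modalities — a 10-sensor metal-oxide gas array
(electronic nose) and near-infrared hyperspectral image cubes — into a
single regression of TP content, designed to hold across tea
*categories* (black, green, yellow), not just within one.

The reference sampling design (`default_variety_table()`) has 10
varieties in 3 categories, 10 or 15 samples each, 110 samples in all,
with per-variety TP mean, SD and range spanning 10.65–29.65% and a
pooled count-weighted mean of 18.78%.

## The synthetic-data generator

No public paired dataset of this design exists, so the package
includes a first-class generator. What it emulates, and what it does
not, determines what the test suite can and cannot show.

**TP contents** are drawn from a normal distribution per variety,
truncated to the variety's published range (`draw_tp()`). Because some
ranges are asymmetric about the published mean, the location parameter
is re-centred numerically so that the *truncated* mean equals the
published mean — the published means are summaries of range-limited
observations. A side effect is that the realised SD is slightly below
the published SD; we accept this rather than inflate the spread
outside the published range.

**E-nose records** (`simulate_enose()`) follow a single-time-constant
saturating rise per sensor, `c_j(t) = 1 + a_j(1 − e^{−t/τ_j})(1+ε_t)`:
the simplest kinetic model consistent with the observed behaviour that
responses stabilise by 55 s (all τ_j ≤ 13 s, so every trace is within
2% of its plateau at t₀ = 55 s). Signs and relative magnitudes follow
the sensor classes: W5S, W1S, W1W, W2S, W2W deviate above 1 (W1W
largest), W1C, W3C, W5C below 1, W6S and W3S stay near 1. The plateau
amplitude is affine in TP with a deterministic variety-level offset
(equal-TP samples of different varieties still smell different) and
three noise components (`tea_noise()`): i.i.d. trace noise (sd 0.01),
a per-sample multiplicative drift common to all sensors (sd 0.06), and
per-sensor amplitude jitter (sd 0.05). The common drift is what caps
the attainable regression accuracy: independent noise would average
away across 10 sensors and 6 statistics, leaving an implausibly
perfect predictor. With all noise off, the steady-state average is an
exact affine, strictly monotone function of TP within a variety — the
hook the parameter-recovery tests rely on.

**Cubes** (`simulate_cube()`) are 64 x 64 x 397 reflectance arrays on
the 908–1700 nm / 2 nm grid: a smooth baseline minus Gaussian
absorption features at 1106 nm (σ = 30 nm) and 1375 nm (σ = 40 nm)
whose depths grow affinely with TP, multiplied by a zero-mean
high-frequency sinusoidal texture field whose amplitude also grows
with TP (so detail sub-band energies carry signal), plus pixel noise
(sd 0.01) inflated fourfold outside 944–1688 nm to motivate the
spectral crop. Depth and texture amplitudes carry per-sample relative
jitter (sd 0.10 and 0.15), which keeps the HSI-only model honest
(validation R² around 0.5–0.7 rather than ≈1). The 64 x 64 spatial
size is a desk-scale choice — the ROI logic is size-independent — and
the absorption/texture slopes were fixed once so that fused-feature
regression on 110 noisy samples lands in a validation-R² band of about
0.85–0.95, the regime the pipeline is designed for.

Not emulated: real sensor drift/aging, radiative-transfer or
scattering physics, inter-sensor cross-sensitivities, spatially
structured leaf morphology. Passing tests therefore demonstrate
correctness of the pipeline and recoverability of a planted
composition signal — not field performance on real teas.

## Feature extraction

**Time domain** (`extract_time_domain()`): six statistics per sensor,
60 named features. The printed definitions are followed literally:
population moments (divisor N) for variance and kurtosis; the
integral is the rectangle-rule sum (the defining text calls it the
total response); the steady-state average uses divisor N − t₀ over
the post-onset values; skewness uses the adjusted Fisher–Pearson
small-sample factor. t₀ = 55 s globally, configurable; per-sample
onset detection is deliberately not implemented (no rule is given for
it). Zero-variance traces make kurtosis/skewness undefined: the
default is an error naming the sensor, with an opt-in sentinel 0 plus
warning (`degenerate = "zero"`).

**Frequency domain** (`extract_cwt_summary()`): a continuous wavelet
transform at dyadic scales 2¹…2¹⁰ per trace; per-sensor energy S_j
sums squared coefficients over the full scale x time plane, and the
two array-level summaries WM = max S_j, WA = mean S_j are appended to
the feature set. Two conventions deserve note. First, the summary is
computed *across* sensors (2 features, not 2 per sensor): this is the
only reading that reconciles the 20-variable e-nose set (18 selected +
WM + WA) used downstream. Second, the mother wavelet is not prescribed
anywhere; we default to the Mexican hat, a common choice for MOS
transients, and record it in the output. The trace is zero-padded
outside its 75-point support, which matters once the scale approaches
the trace length; energies remain finite and comparable across
sensors. No installed R package provides a CWT, so the transform is a
direct convolution implementation (`cwt_trace()`), tested by its
quadratic-homogeneity and degenerate-input properties.

**HSI** (`extract_hsi_features()`): the centered 50 x 50 ROI mean
spectrum per band (`extract_roi_spectrum()`), cropped to the closed
interval 944–1688 nm. The oft-quoted "457 bands" for this window is
inconsistent with a 2 nm grid ((1688 − 944)/2 + 1 = 373); we crop by
wavelength interval and let the band count follow. Feature wavelengths
default to 1106/1375 nm and can be re-derived by the successive
projections algorithm (`spa_select()`): projection chains from every
start band, scored by multilinear-regression RMSE on a deterministic
systematic validation split (samples ordered by target, every third
held out), ties broken toward lower band indices. Requested
wavelengths snap to the nearest band on the cropped axis (1375 nm
snaps to 1374 on the 2 nm grid); the snap is deterministic.

Band images are decomposed by a 2-level Daubechies DWT (`dwt2()`,
default db4, filters frozen from the standard published coefficients).
We use **periodized** boundaries rather than symmetric extension: only
a periodized orthonormal transform conserves energy exactly, and
energy partitioning (Parseval to 1e−9 relative) is one of the
package's acceptance invariants. Odd intermediate lengths (25 after
one level of a 50-pixel ROI) are circularly extended by one sample.
Per detail sub-band Λ ∈ {LH, HL, HH} at levels 1–2 we report the
energy WE (mean squared coefficient) and entropy WEN. The printed
entropy formula applies log₂ to raw coefficients, which are routinely
negative; we implement the standard normalized-energy Shannon entropy
(p = coefficient²/sub-band energy, 0·log 0 ≔ 0, scaled by 1/MN) and
document this as a deliberate deviation. Sub-bands whose energy is
floating-point residue (a constant image leaves ~1e−33 in the detail
bands) are treated as zero for the entropy, via a relative threshold
of 1e−24 x image energy.

## Selection and fusion

E-nose features are selected per family: one boosted-tree regressor
per statistic family on its 10 sensor features, scored by split count
(F-score, the number of times a feature divides a node — not gain),
keeping the top ceil(0.30 x 10) = 3 sensors per family, 18 names in
all. A single 60-feature model would not honour the 3-per-family
structure. HSI features are ranked by |Pearson r| against TP, keeping
round(0.25 x 24) = 6, ties by name order; zero-variance features score
0 with a warning. WM and WA bypass selection (they are array-level
summaries) and are always appended. Fusion is ordered concatenation:
20 + 6 = 26 variables. Selection runs on the calibration set only —
stricter than strictly necessary, but leakage-safe.

## Modeling and evaluation

The calibration/validation split (`stratified_split()`) is stratified
by variety: 3 validation samples per variety (7/3 for 10-sample,
12/3 for 15-sample varieties), giving 80/30 — the unique near-7:3
per-variety allocation consistent with those totals. Min–max
normalization is fitted on the calibration table only; applied values
are not clipped.

Three regressors are grid-searched within their published ranges
(`model_grid()`): epsilon-SVR with RBF kernel (reading the libsvm
parameter codes: c = cost ∈ (0, 20], g = γ ∈ (0, 10], s = 3 the
epsilon-SVR type, p = ε ∈ [0.001, 1]); a random forest with
n_estimators ∈ [100, 2000], max_depth ∈ [1, 10], bootstrap off (each
tree sees the full calibration set, randomness via feature
subsampling) and permutation importance computed once — implemented
with `ranger`, whose `max.depth`/`replace`/`sample.fraction`/
`importance` switches map onto exactly those semantics (the classic
`randomForest` flags `importance`/`nPerm` have no depth cap); and
XGBoost over learning_rate, n_estimators, max_depth, gamma, subsample,
min_child_weight. Grid granularity is not prescribed, so `model_grid()`
offers a default ladder (every published optimum is a member) and a
coarse ladder for repeated simulation studies; model choice uses
5-fold cross-validated RMSE on the calibration set, first minimum in
grid order winning. All fits are single-threaded and seeded, so a
fixed seed reproduces the winning parameters bit-for-bit.

Evaluation reports R² = 1 − SS_res/SS_tot, RMSE, and adjusted
R² = 1 − (1 − R²)(n − 1)/(n − p − 1) with p the number of model
features and n the set size. Note a known discrepancy in the source
material this design follows: its printed adjusted-R² values do not
satisfy this formula at the stated n = 30, p = 26 (R² = 0.900 gives
0.033, not 0.750). We follow the formula verbatim; at p = 26 and
n = 30 the penalty is severe and adjusted R² on the validation set is
mostly of diagnostic value.

## Problem sizes and determinism

The test suite and acceptance script run everything at the design
scale (110 samples, 64 x 64 x 397 cubes). The fusion-advantage
recovery suite uses 20 seeded replicates with the coarse grid ladder
(a sign test on fused-vs-HSI validation R² per algorithm); the
acceptance script runs one full study with the default ladder. Cubes
are streamed one at a time (about 1.4 GB would otherwise sit in
memory for a full in-memory dataset); every stochastic step derives
child seeds from the user seed, so whole studies are reproducible.

## Known limitations

- The generator's realism limits are listed above; in particular the
  within-variety TP–amplitude relation is exactly affine, which favours
  tree and kernel methods about equally and says nothing about real
  sensor nonlinearity.
- SPA scores candidate chains with ordinary least squares; for
  near-collinear chains the redundant direction is dropped (coefficient
  zeroed) rather than regularised.
- The CLI stores trained models as RDS files (R's native
  serialisation); JSON export of a fitted SVR/forest is not attempted.
- `adjusted_r_squared()` errors for n ≤ p + 1 rather than returning a
  signed infinity; evaluation reports NA in that case.
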