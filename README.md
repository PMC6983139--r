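# teafuse

Nondestructive estimation of tea polyphenol (TP) content — in mass
percent — across tea categories (black, green, yellow) by fusing two
sensing modalities:

- an **electronic nose**: a 10-element metal-oxide gas-sensor array
  (W1C, W5S, W3C, W6S, W5C, W1S, W1W, W2S, W2W, W3S) whose
  conductance-ratio response curves, sampled at 1 Hz for 75 s, form a
  sample's scent fingerprint;
- **near-infrared hyperspectral imagery**: reflectance cubes over
  908–1700 nm whose absorption depth and spatial texture at informative
  wavelengths co-vary with composition.

The package is aimed at chemometricians and food-quality researchers who
want a reproducible, end-to-end implementation of the
time-domain + frequency-domain feature-fusion pipeline, together with a
synthetic-data generator that emulates the 10-variety / 110-sample
cross-category study design it was developed for.

## The method

Per sample, the pipeline computes:

1. **E-nose time-domain features** (6 statistics x 10 sensors = 60):
   variance `VAR = (1/N) Σ (cᵢ − c̄)²`, integral `INV = Σ cᵢ Δt`,
   steady-state average `RSAV = (1/(N − t₀)) Σ_{i>t₀} cᵢ` (t₀ = 55 s),
   average differential `ADV = (1/(N−1)) Σ (cᵢ₊₁ − cᵢ)/Δt`, excess
   kurtosis `m₄/m₂² − 3`, and adjusted skewness
   `√(N(N−1))/(N−2) · m₃/m₂^{3/2}`.
2. **E-nose frequency-domain summaries**: a Mexican-hat CWT at dyadic
   scales 2¹…2¹⁰ per trace; per-sensor energy `Sⱼ = Σ Xᵢ²` over the
   scale x time plane, summarised across the array as `WM = max Sⱼ` and
   `WA = mean Sⱼ`.
3. **HSI features**: mean spectrum over the centered 50 x 50-pixel ROI,
   cropped to 944–1688 nm; two feature wavelengths (1106 and 1375 nm by
   default, or re-derived by the successive projections algorithm); per
   band image a 2-level Daubechies (db4) DWT with wavelet energy
   `WE = (1/MN) Σ |I^Λ|²` and normalized-energy entropy `WEN` for each
   detail sub-band Λ ∈ {LH, HL, HH} — 24 features.
4. **Selection and fusion**: per-family boosted-tree split-count
   importance keeps the top 30% of sensors (3 x 6 = 18 features; WM and
   WA are always appended → 20 e-nose variables); Pearson correlation
   keeps the top 25% of the 24 HSI features (6); fusion gives 26
   variables.
5. **Regression**: min–max normalization (Eq. fitted on calibration
   only), then grid-searched epsilon-SVR (RBF), random forest, or
   XGBoost, evaluated on a variety-stratified 80/30
   calibration/validation split with R², adjusted
   R² `= 1 − (1 − R²)(n−1)/(n−p−1)`, and RMSE.

## Worked example

```r
library(teafuse)

st <- tp_fusion_study(seed = 7, algorithms = "xgboost",
                      feature_sets = c("hsi", "fusion"),
                      granularity = "coarse")
st$results[, c("algorithm", "features", "variables", "val_R2", "val_RMSE")]
#>   algorithm features variables    val_R2 val_RMSE
#> 1   xgboost      hsi         6 0.6221469 3.209295
#> 2   xgboost   fusion        26 0.9058248 1.602199
```

The run simulates 110 paired samples, extracts and selects features,
and fits a grid-searched XGBoost regressor on 80 calibration samples.
The printed rows say: with the 6 correlation-selected hyperspectral
features alone, validation R² is 0.62 (RMSE 3.2% TP); adding the 20
selected e-nose features (26 fused variables) lifts validation R² to
0.91 (RMSE 1.6% TP) — the fusion advantage the pipeline is built to
deliver.

Lower-level entry points: `simulate_tea_dataset()`, `simulate_enose()`,
`simulate_cube()`, `extract_time_domain()`, `extract_cwt_summary()`,
`extract_roi_spectrum()`, `spa_select()`, `extract_hsi_features()`,
`importance_select_enose()`, `correlation_select_hsi()`,
`fuse_features()`, `stratified_split()`, `tp_train()`,
`evaluate_model()`. A command-line interface with `simulate`,
`extract-enose`, `extract-hsi`, `select`, `train`, `evaluate` and
`predict` subcommands is installed at
`system.file("scripts", "teafuse", package = "teafuse")`; on-disk
formats are long-form CSV for sensor traces, ENVI header/binary pairs
for cubes, CSV feature tables, and JSON reports.

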