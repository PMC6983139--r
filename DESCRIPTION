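Package: teafuse
Title: Tea Polyphenol Estimation by Fusing Electronic-Nose and
    Hyperspectral-Image Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction, fusion, and regression for nondestructive
    estimation of tea polyphenol content across tea categories. Extracts
    time-domain statistics and continuous-wavelet energy summaries from
    metal-oxide gas-sensor (electronic nose) response curves, and two-level
    Daubechies wavelet energy/entropy features from near-infrared
    hyperspectral image cubes; selects features by boosted-tree split-count
    importance and Pearson correlation; and fits grid-searched support
    vector, random forest, and gradient-boosted regressors with stratified
    calibration/validation evaluation. Includes a synthetic-data generator
    emulating the multi-variety sampling design, readers and writers for
    the on-disk formats (long-form sensor CSV, ENVI cubes, feature tables),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
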