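Package: esrindex
Title: Data-Driven Epidemiological Susceptibility Risk Indices from Country Indicator Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constructs composite epidemiological susceptibility risk (ESR)
    indices from country-by-variable-by-year indicator panels. Implements
    per-year principal component analysis in classical, robust (principal
    component pursuit) and robust sparse variants, and a three-stage dynamic
    factor model (per-country EM estimation, cross-country sparse vector
    autoregression, joint Kalman smoothing). Includes panel input/output,
    imputation and per-year standardization, reconstruction R-squared with
    percentile trimming, augmented Dickey-Fuller stationarity and
    Kaiser-Meyer-Olkin adequacy diagnostics, a cross-validated predictive-power
    harness, and a synthetic-panel generator with ground truth for recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    nnet,
    withr
Config/testthat/edition: 3
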