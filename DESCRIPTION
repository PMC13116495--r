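Package: ppcwatch
Title: Postoperative Pulmonary Complication Risk Prediction and Nursing
    Surveillance Recommendations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for postoperative pulmonary complication (PPC)
    surveillance on tabular electronic-medical-record style data: a
    synthetic postoperative cohort generator with planted class-conditional
    structure, abnormality-flag derivation from configurable vital-sign
    normal ranges, a hybrid risk classifier coupling a tabular neural
    encoder (SHAP-importance-weighted inputs, imbalance-aware training)
    with a random-forest head and a tuned decision threshold, a
    seven-metric evaluation panel with bootstrap confidence intervals,
    ablation and hyperparameter-search utilities, and a deterministic
    rule engine that turns assessed abnormalities and predicted risk into
    validated action-evidence-rationale nursing surveillance
    recommendations in a structured JSON format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
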