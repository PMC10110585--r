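Package: renalsplit
Title: Split Renal Function Estimation and New Baseline GFR Prediction
    After Radical Nephrectomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates split renal function (SRF) from parenchymal volumes,
    either software-derived volume triplets or ellipsoid approximations from
    linear length/width/height (LWH) measurements, and predicts the new
    baseline glomerular filtration rate (NBGFR) after radical nephrectomy with
    the renal-functional-compensation model NBGFR = RFC x GlobalGFR x SRF.
    Includes CKD-EPI creatinine equations (2009 and 2021), a clinical cohort
    simulator with per-method SRF measurement noise, and a prediction-model
    evaluation suite (Pearson r, bias, precision, mean squared error, P30
    accuracy, threshold ROC AUC) with paired patient-level bootstrap
    confidence intervals and method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
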