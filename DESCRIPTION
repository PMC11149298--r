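Package: paki3
Title: Prediction of Persistent Acute Kidney Injury Stage 3 in the ICU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for early prediction of persistent acute
    kidney injury stage 3 (pAKI3) from irregular ICU electronic health record
    time series. Implements hourly KDIGO staging from serum creatinine, urine
    output and renal replacement therapy; the composite persistence endpoint
    (stage 3 lasting 72 h, stage 3 of 48 h ending in death, or renal
    replacement therapy after more than 24 h of stage 3); the cohort
    inclusion/exclusion cascade; rolling-window feature engineering over
    thirteen routinely collected variables; a gradient-boosted-tree risk
    scorer with sensitivity-targeted threshold calibration; per-stay
    maximum-alarm (MAX metric) evaluation with prevalence-standardized
    predictive values and equalized-odds fairness auditing; and a synthetic
    ICU cohort generator so the whole pipeline is testable without access to
    clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    xgboost,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    arrow,
    pROC
Config/testthat/edition: 3
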