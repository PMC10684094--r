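Package: fuzznet
Title: Interpretable Fuzzy Rule Networks for Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits interpretable fuzzy rule-based neural networks for tabular
    clinical risk prediction. Continuous measurements are encoded into low,
    medium and high fuzzy concepts by smoothed trapezoidal membership
    functions; rules are conjunctions computed with a parameterized T-norm
    that interpolates between product and minimum, and class scores are
    disjunctions computed with a parameterized T-conorm interpolating
    between sum and maximum (the tropical, min/max, limit yields crisp rule
    logic). Supports clinical-knowledge rule initialization, sparsity and
    rule-decorrelation regularization, rule extraction and cross-fold
    ensembling, inference of concept transition ranges in clinical units,
    and per-sample fired-rule explanations. Includes a longitudinal
    EHR-style preprocessing pipeline (encounter pairing, derived features,
    carry-forward plus stochastic imputation, patient-wise cross-validation)
    and a synthetic cohort generator with planted rules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
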