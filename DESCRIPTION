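Package: mosr
Title: Multi-Objective Symbolic Regression for One-Year Postoperative
    Mortality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic-programming symbolic regression for imbalanced binary
    classification of 1-year mortality after major non-cardiac surgery,
    jointly optimising binary cross-entropy and F1 score with NSGA-II style
    Pareto selection. Includes a synthetic perioperative cohort generator
    emulating the marginal structure of a clinical plus cardiopulmonary
    exercise testing (CPET) feature table with a planted logistic outcome
    mechanism, the full evaluation protocol (stratified 80/20 split,
    grid-search 10-fold cross-validation with an inner 90/10 division,
    repeated test-subset evaluation, calibration bins), and model-agnostic
    Shapley-value feature attribution with exact enumeration and a
    permutation-sampling estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
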