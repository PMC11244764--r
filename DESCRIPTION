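Package: vicloud
Title: Shapley Variable Importance Cloud for Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses variable importance from an ensemble of nearly optimal
    logistic regression models (a Rashomon set) rather than from a single
    fitted model. Near-optimal models are sampled around the maximum
    likelihood fit by randomly rescaling its coefficient covariance; each
    model's global Shapley (SAGE-style) importance is estimated by
    permutation sampling with grouped one-hot columns, and per-model
    estimates are pooled by random-effects meta-analysis to obtain overall
    importance with a 95% prediction interval and a significance flag.
    Includes importance-prescreened backward-AIC model building, test-set
    evaluation (AUC, corner-optimal threshold, classification metrics with
    bootstrap confidence intervals), and a Gaussian-copula synthetic cohort
    generator emulating an out-of-hospital cardiac arrest registry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    MASS,
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
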