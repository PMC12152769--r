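Package: combatls
Title: Location- and Scale-Preserving Multi-Site Harmonization with
    Normative Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes multi-site tabular features (for example regional
    brain volumes, cortical thickness and surface area) with the ComBat
    family of empirical-Bayes batch-effect estimators, including a
    location-scale variant (ComBatLS) that preserves covariate effects on
    each feature's log-linear scale as well as its mean.  Also provides a
    Box-Cox Cole-Green normative-scoring engine (growth-chart style
    centiles and z-scores), a synthetic sex-imbalanced-site cohort
    simulator, and the evaluation statistics needed to quantify centile
    errors, sex biases, and residual site effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    mgcv,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
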