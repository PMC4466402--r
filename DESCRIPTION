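Package: paleoSDM
Title: Presence-Only Species Distribution Models with Paleoclimate
    Hindcasting and Biotic-Interaction Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for presence-only ecological niche modelling of
    interacting species across climate scenarios. Provides lightweight gridded
    climate layers with ESRI ASCII input/output, environmental-space occurrence
    filtering for balanced calibration data, a Bioclim percentile-envelope model
    and an L1-regularized maximum-entropy (MaxEnt-style) model, evaluation by
    rank-based AUC, omission rate, the max-sensitivity-plus-specificity
    threshold and small-sample AICc with relative likelihoods, projection onto
    past climate scenarios with circulation-model ensemble averaging,
    range-stability classification over glacial timescales, and comparison of
    models with and without a host-species presence predictor. A virtual-species
    simulator generates climate scenario sets and host/parasite occurrences with
    known ground truth for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
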