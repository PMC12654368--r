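Package: odortools
Title: Predicting Aroma Contribution and Odor Detection Thresholds of Volatile Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether a volatile compound contributes
    positively or negatively to an aroma and for estimating its odor detection
    threshold from molecular structure. Provides compound registration and
    SMILES canonicalization, rule-based curation of free-text odor descriptors
    into semantic categories and binary contribution labels, molecular
    featurization (ECFP4/ECFP6/MACCS fingerprints plus physicochemical
    descriptors), Murcko scaffold-aware train/validation splitting, a model
    harness (random forest, gradient-boosted trees, multilayer perceptron and
    graph convolutional network families) with randomized hyperparameter search
    and class-imbalance handling, a full evaluation suite including residual
    based conformal prediction intervals, an ascending-series sensory panel
    estimator of group odor thresholds with panelist bootstrap confidence
    intervals, odor activity value (OAV) ranking of candidate aroma compounds,
    and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
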