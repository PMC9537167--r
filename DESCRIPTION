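Package: dtiarray
Title: Array-Type Meta-Predictors of Cholinergic Drug-Target Interactions
    for Chemical-Warfare-Agent-Likeness Detection
Version: 0.1.0
Authors@R:
    person("dtiarray", "maintainers", email = "dtiarray@example.org",
           role = c("aut", "cre"))
Description: Builds a grid of binary drug-target-interaction classifiers
    (random forest, decision tree, support-vector machine, k-nearest
    neighbour) for five cholinergic targets (nAChR, mAChR, AChE, BuChE,
    VAChT) from circular fingerprints (ECFP/FCFP) of compound structures,
    assembles the per-compound predictions of the full 200-model grid into
    ordered 2D/3D binary arrays, and trains a small convolutional network
    on those arrays to detect chemical-warfare-agent-likeness under severe
    class imbalance. Includes data cleaning and binarization for
    ChEMBL-export-style activity tables, a full confusion/ranking metric
    suite (MCC, F1, balanced-accuracy AUC, ROC-AUC, AUPR), SMOTE
    oversampling and duplicate-array undersampling regimes, an equal-depth
    MLP baseline, and synthetic-data generators with planted
    structure-activity signal so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    FNN,
    quadprog,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
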