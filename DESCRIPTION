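Package: hergqsar
Title: Ligand-Based Classification of hERG Potassium-Channel Blockade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete QSAR workflow for classifying small molecules as
    blockers or non-blockers of the hERG cardiac potassium channel from
    ChEMBL-style activity exports: activity-record curation (assay filters,
    SMILES standardization, pIC50 conversion, replicate aggregation with a
    sigma > 2 outlier rule, dual potency thresholds), open 2D molecular
    descriptors with pruning and z-normalization, per-class MaxMin diversity
    splitting on Morgan fingerprints, three-step random-forest feature
    selection, SMOTE oversampling and balanced random forests for class
    imbalance, six tunable classifier families with stratified 5-fold
    cross-validation, a leverage-based applicability domain (h > 3p/n), an
    abstaining consensus predictor, and the standard confusion-matrix metric
    suite (SE, SP, BA, MCC, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    class,
    nnet,
    rpart,
    randomForest,
    e1071,
    xgboost,
    igraph,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
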