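Package: sdcfe
Title: Synergistic Discriminative Class Feature Extraction for Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for high-dimensional transcriptomic and
    methylation matrices by a synergistic score that blends a MAD-regularized
    between/within class variance ratio (a robust Fisher-like discriminative
    score) with an unsupervised cluster-separation statistic (one-way ANOVA F
    across K-means clusters). Includes the surrounding analysis toolkit:
    matrix preprocessing (missingness filtering, KNN imputation, log2
    transform, z-score scaling, clinical matching, feature-list alignment),
    selection-set algebra (intersection, non-redundant union, multiomics late
    fusion), gradient-boosting importance ranking via an adapter, biomarker
    novelty tiering from a binary evidence table, a nearest-centroid baseline
    classifier, multi-class evaluation metrics (balanced accuracy, macro-F1,
    MCC, macro one-vs-rest AUC, macro expected calibration error), and a
    synthetic-data generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
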