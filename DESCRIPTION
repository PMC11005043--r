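Package: fcaflow
Title: Sequence, Structure and Molecular-Dynamics Biodescriptors for
    Enzyme Variant Activity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting the fold change in
    activity (FCA) of enzyme variants from integrated biodescriptors:
    66 physicochemical scale features and 14 global sequence properties,
    32 molecular-dynamics features (superposed RMSD, radius of gyration
    and DSSP-style secondary-structure fractions over replicate
    trajectories), and 80 binding-pocket descriptors (geometry, solvent
    accessibility, chemistry, occupancy and normalized B-factors).
    Includes trajectory robustness diagnostics (chunked one-way ANOVA,
    Hausdorff path-similarity analysis with Ward clustering, shuffle
    retention tests), a model benchmarking protocol (default-parameter
    screening with exclusion rules, random hyperparameter search,
    bootstrap comparison of feature-block subsets with Tukey HSD), and
    interpretability diagnostics (permutation importance, tree gain and
    split rankings, exact small-model Shapley values, SHAP summaries,
    and hypergeometric error enrichment). A seeded synthetic-data
    generator produces variant libraries, replicate toy trajectories and
    a planted response so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
LinkingTo: Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    bio3d,
    Biostrings,
    glmnet,
    rpart,
    ranger,
    xgboost,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'aa-data.R'
    'io-formats.R'
    'dataset-assembly.R'
    'fcaflow-package.R'
    'model-bench.R'
    'interpretation.R'
    'utils.R'
    'trajectory-features.R'
    'pocket-features.R'
    'sequence-layer.R'
    'synthetic-data.R'
    'pipeline.R'
    'robustness-stats.R'
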