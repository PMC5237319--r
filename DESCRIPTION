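Package: mvibench
Title: Benchmarking Missing-Value Imputation for Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation framework for the objective comparison of
    missing-value imputation algorithms on gene-expression matrices.
    Complete matrices are masked completely at random at five missing
    percentages, imputed with fourteen built-in algorithms (zero and
    row-average baselines, SVD and Bayesian PCA global methods, and the
    KNN, LS and local-least-squares families including sequential,
    iterative and shrinkage variants) or with user-supplied executable
    plugins, and scored with three performance indices: the inverse
    normalized root mean square error (1/NRMSE), the cluster pair
    proportion (CPP) and the biomarker list concordance index (BLCI).
    Per-algorithm scores are aggregated into an overall ranking score
    (ORS) and an overall normalized score (ONS). A synthetic-data
    generator with planted gene clusters and differentially expressed
    genes provides ground truth for testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'expr-matrix.R'
    'matrix-io.R'
    'synthetic.R'
    'masking.R'
    'imputers.R'
    'impute-knn.R'
    'impute-global.R'
    'impute-ls.R'
    'plugins.R'
    'indices.R'
    'evaluation.R'
    'aggregation.R'
    'tidiers.R'
    'config.R'
    'mvibench-package.R'
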