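Package: lnflare
Title: Knowledge-Incorporated Prediction of Treatment Response After Renal
    Flare in Lupus Nephritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a disease-defining gene (DDG) signature for lupus
    nephritis from network hub analysis of differential expression (MCODE
    module detection plus five CytoHubba centralities), validates it with a
    single-sample GSEA (ssGSEA) permutation null, projects its per-sample
    activity onto an immunology gene panel through pooled Spearman
    correlations and K-means clustering to form disease-defining clusters
    (DDCs), and trains per-cluster SMOTE-balanced LASSO classifiers of
    treatment response after the first renal flare, evaluated by ROC/AUC
    with DeLong confidence intervals and confusion-matrix metrics. Includes
    synthetic-data generators with machine-checkable ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
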