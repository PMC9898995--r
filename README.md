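# lnflare

Knowledge-incorporated prediction of treatment response after the first
renal flare in lupus nephritis (LN).

Proliferative LN patients who flare after remission respond unevenly to
induction therapy, and the predictive signal lives in a ~500-gene targeted
immunology panel measured on small cohorts — a setting where a classifier
fitted to all genes at once overfits. `lnflare` implements a pipeline that
constrains feature selection with disease biology before any supervised
learning:

1. **DDGs** — a disease-defining gene signature from case/control kidney
   transcriptomes: empirical-Bayes moderated t-tests (BH-adjusted, no logFC
   threshold), intersection of per-compartment DEG sets, MCODE module
   detection on the up-/down-regulated interaction networks (modules
   admitted at score > 3 and > 5 nodes), and five hub centralities
   (degree, MNC, DMNC with ε = 1.7, MCC, EPC) aggregated over top-10 lists
   with a degree ≥ 10 filter.
2. **Validation** — per-sample ssGSEA activity of the signature
   (rank-weight exponent α = 0.25), compared case vs control against a
   permutation null of 1000 random same-size gene sets:
   `empirical_p = (1 + #{background ≥ observed}) / (n_perm + 1)`.
3. **DDCs** — disease-defining clusters: Spearman's ρ between the DDG
   ssGSEA score and each panel gene, pooled across datasets (datasets
   missing > 5 signature genes are excluded), then K-means (Lloyd,
   k-means++ seeding, best of 25 restarts) with an elbow rule on the WSS
   curve.
4. **Response models** — per cluster: stratified 8:2 split, SMOTE balancing
   of the training minority (k = 5), L1-penalized logistic regression with
   tenfold cross-validated deviance, AUC with DeLong 95% CIs on train/test/
   entire sets, and external-validation confusion-matrix metrics
   (accuracy, precision = TP/(TP+FP), recall = TP/(TP+FN), F1).

Every stage has a synthetic-data generator with planted ground truth
(shared DEG programs, a latent hub activity, correlation blocks, planted
predictive genes at a 2.76:1 class imbalance, planted network modules), so
the whole pipeline is testable offline.

## Worked example

```r
library(lnflare)

manifest <- run_pipeline(ln_config(seed = 1), out_dir = "lnflare_run")
res <- manifest$results

length(res$ddgs$sets$ddg)        # DDG signature size
#> [1] 47
res$permutation$empirical_p      # signature vs 1000 random gene sets
#> [1] 0.000999001
res$logfc_rho                    # common-DEG logFC concordance across compartments
#> [1] 0.9753165
glance(res$ddc)                  # 8 clusters over 500 panel genes
#> # A tibble: 1 x 4
#>       k n_genes tot_wss  seed
#>   <int>   <int>   <dbl> <int>
#> 1     8     500    12.4 87866

dplyr::select(res$models, cluster, n_selected, auc_test, accuracy,
              precision, recall, f1)[1, ]
#> # A tibble: 1 x 7
#>   cluster n_selected auc_test accuracy precision recall    f1
#>   <chr>        <int>    <dbl>    <dbl>     <dbl>  <dbl> <dbl>
#> 1 DDC-8           36    0.953    0.865     0.915  0.896 0.905
```

The top-ranked model is the cluster holding the planted predictive genes:
its test AUC (0.953 here) dominates the other seven clusters (which hover
near 0.5 because their blocks carry no label signal), and all five planted
genes appear among its LASSO selections. Stage outputs (DEG tables, the
DDG GMT, the correlation profile, cluster assignments, the model summary
CSV and a digest manifest) are written under `out_dir`; re-running with the
same configuration reproduces them byte for byte.

Individual stages are exposed directly — `moderated_t_test()`,
`mcode_modules()`, `centrality_scores()`, `ssgsea_matrix()`,
`permutation_null()`, `build_correlation_profile()`, `kmeans_cluster()`,
`smote()`, `lasso_cv()`, `run_per_cluster_models()` — each taking and
returning ordinary matrices/tibbles, with `tidy()`/`glance()`/`autoplot()`
methods on the fitted objects.

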