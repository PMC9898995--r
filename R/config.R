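#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline with its default. The
#' defaults encode the analysis constants (MCODE score > 3 and > 5 nodes for
#' the DDG criterion, top-10 hub aggregation with degree < 10 exclusion, 1000
#' permutations, 8 clusters, 8:2 train/test split, tenfold CV, |logFC| >= 1
#' for response DEGs) plus canonical method parameters the analysis does not
#' print (ssGSEA exponent 0.25, DMNC exponent 1.7, MCODE vertex-weight
#' percentage 0.2).
#'
#' @param seed Master seed; per-stage seeds are spawned deterministically.
#' @param alpha_ssgsea ssGSEA rank-weight exponent.
#' @param epsilon_dmnc DMNC density exponent.
#' @param mcode_vwp MCODE vertex weight percentage (0-1).
#' @param mcode_haircut,mcode_fluff MCODE post-processing flags.
#' @param mcode_max_depth MCODE growth depth limit from each seed node.
#' @param min_mcode_score,min_mcode_nodes DDG module admission criteria
#'   (strict inequalities: score > 3, nodes > 5).
#' @param hub_topk Top-k per centrality method.
#' @param min_degree_keep Degree threshold below which top-k genes are
#'   excluded.
#' @param epc_iters Monte-Carlo iterations for the EPC centrality.
#' @param n_perm Permutation count for the signature null.
#' @param k_clusters Number of disease-defining clusters, or `"auto"` for the
#'   second-elbow rule over k = 2..15.
#' @param kmeans_restarts Random restarts for K-means.
#' @param max_missing_genes Datasets missing more signature genes than this
#'   are excluded from the correlation profile.
#' @param split_ratio Training fraction of the response cohort.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param cv_folds Cross-validation folds for the LASSO.
#' @param logfc_threshold_response |logFC| threshold flag for response DEGs.
#' @param alpha_bh BH-adjusted significance level.
#' @return A validated named list of class `ln_config`.
#' @export
ln_config <- function(seed = 1L,
                      alpha_ssgsea = 0.25,
                      epsilon_dmnc = 1.7,
                      mcode_vwp = 0.2,
                      mcode_haircut = TRUE,
                      mcode_fluff = FALSE,
                      mcode_max_depth = 100L,
                      min_mcode_score = 3,
                      min_mcode_nodes = 5L,
                      hub_topk = 10L,
                      min_degree_keep = 10L,
                      epc_iters = 100L,
                      n_perm = 1000L,
                      k_clusters = 8L,
                      kmeans_restarts = 25L,
                      max_missing_genes = 5L,
                      split_ratio = 0.8,
                      smote_k = 5L,
                      cv_folds = 10L,
                      logfc_threshold_response = 1,
                      alpha_bh = 0.05) {
  cfg <- list(seed = as.integer(seed), alpha_ssgsea = alpha_ssgsea,
              epsilon_dmnc = epsilon_dmnc, mcode_vwp = mcode_vwp,
              mcode_haircut = isTRUE(mcode_haircut),
              mcode_fluff = isTRUE(mcode_fluff),
              mcode_max_depth = as.integer(mcode_max_depth),
              min_mcode_score = min_mcode_score,
              min_mcode_nodes = as.integer(min_mcode_nodes),
              hub_topk = as.integer(hub_topk),
              min_degree_keep = as.integer(min_degree_keep),
              epc_iters = as.integer(epc_iters),
              n_perm = as.integer(n_perm),
              k_clusters = if (identical(k_clusters, "auto")) "auto" else as.integer(k_clusters),
              kmeans_restarts = as.integer(kmeans_restarts),
              max_missing_genes = as.integer(max_missing_genes),
              split_ratio = split_ratio,
              smote_k = as.integer(smote_k),
              cv_folds = as.integer(cv_folds),
              logfc_threshold_response = logfc_threshold_response,
              alpha_bh = alpha_bh)
  if (!(cfg$mcode_vwp > 0 && cfg$mcode_vwp < 1)) ln_stop("mcode_vwp must be in (0,1)")
  if (!(cfg$split_ratio > 0 && cfg$split_ratio < 1)) ln_stop("split_ratio must be in (0,1)")
  if (cfg$n_perm < 1) ln_stop("n_perm must be >= 1")
  if (cfg$cv_folds < 2) ln_stop("cv_folds must be >= 2")
  if (!identical(cfg$k_clusters, "auto") && cfg$k_clusters < 2)
    ln_stop("k_clusters must be >= 2 or \"auto\"")
  structure(cfg, class = "ln_config")
}

#' Read a run configuration from YAML
#'
#' Unknown fields are a hard error naming the field, as are missing required
#' fields implied by [ln_config()]'s signature (all fields have defaults, so
#' an empty file is a valid configuration).
#'
#' @param path Path to a YAML file whose keys match [ln_config()] arguments.
#' @return An `ln_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(ln_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    ln_stop("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  do.call(ln_config, vals)
}
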