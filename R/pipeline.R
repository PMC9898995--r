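#' Run the full synthetic-study pipeline
#'
#' Orchestrates the end-to-end flow on synthetic data generated under one
#' master seed: simulate discovery datasets; per-dataset moderated-t DEGs
#' and their intersection; up-/down-regulated interaction networks with the
#' hub program planted; MCODE module detection and DDG signature selection;
#' the ssGSEA permutation null for the signature; the panel cohort,
#' pooled correlation profile and K-means disease-defining clusters; the
#' response cohort with an external validation draw, response DEGs, their
#' per-cluster overlap, per-cluster SMOTE+LASSO models and hub re-ranking of
#' the best cluster's selected genes. All stage outputs are written as
#' plain-text files under `out_dir` and digested into a manifest, so a
#' re-run with the same configuration is byte-identical.
#'
#' @param config An [ln_config()], or a path to a YAML file for
#'   [read_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress and elapsed times.
#' @return A `pipeline_manifest` list: `config`, per-stage `seeds`,
#'   `digests` (file -> md5), `results` (the in-memory stage objects) and
#'   `version`.
#' @export
run_pipeline <- function(config = ln_config(), out_dir = tempfile("lnflare_"),
                         verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "ln_config")) config <- do.call(ln_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stats::setNames(
    vapply(1:8, function(i) spawn_seed(config$seed, i), integer(1)),
    c("discovery", "network", "permutation", "panel", "kmeans", "response",
      "validation", "models"))
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] done in %.1fs (seed %d)", stage,
                    as.numeric(Sys.time()) - t0,
                    seeds[[stage]] %||% NA_integer_))
  results <- list()

  t0 <- as.numeric(Sys.time())
  disc <- simulate_discovery_datasets(seed = seeds[["discovery"]])
  results$discovery_truth <- disc$truth
  say("discovery", t0)

  t0 <- as.numeric(Sys.time())
  degs <- lapply(disc$datasets, moderated_t_test,
                 case_label = "LN", control_label = "control")
  names(degs) <- vapply(disc$datasets, function(d) d$dataset_id, character(1))
  sig_up <- lapply(degs, function(d) d$gene[d$q < config$alpha_bh & d$direction == "up"])
  sig_dn <- lapply(degs, function(d) d$gene[d$q < config$alpha_bh & d$direction == "down"])
  venn <- intersect_deg_sets(lapply(degs, function(d) d$gene[d$q < config$alpha_bh]))
  common_up <- Reduce(intersect, sig_up)
  common_dn <- Reduce(intersect, sig_dn)
  results$degs <- degs
  results$venn <- venn
  common_degs <- venn$common
  results$logfc_rho <- logfc_concordance(
    dplyr::filter(degs[[1]], .data$gene %in% common_degs),
    dplyr::filter(degs[[2]], .data$gene %in% common_degs))
  say("discovery", t0)

  t0 <- as.numeric(Sys.time())
  hub_up <- intersect(disc$truth$planted_hub_genes, common_up)
  hub_dn <- intersect(disc$truth$planted_hub_genes_down, common_dn)
  up_net <- simulate_network(node_names = common_up,
                             planted_members = list(hub_up),
                             background_p = 0.02, seed = seeds[["network"]])
  dn_net <- simulate_network(node_names = common_dn,
                             planted_members = list(hub_dn),
                             background_p = 0.02,
                             seed = spawn_seed(seeds[["network"]], 2))
  up_mods <- mcode_modules(up_net$network, vwp = config$mcode_vwp,
                           haircut = config$mcode_haircut,
                           fluff = config$mcode_fluff,
                           max_depth = config$mcode_max_depth)
  dn_mods <- mcode_modules(dn_net$network, vwp = config$mcode_vwp,
                           haircut = config$mcode_haircut,
                           fluff = config$mcode_fluff,
                           max_depth = config$mcode_max_depth)
  ddgs <- select_ddgs(up_mods, dn_mods, min_score = config$min_mcode_score,
                      min_nodes = config$min_mcode_nodes)
  hubs <- top_k_aggregate(
    all_centralities(up_net$network, epc_iters = config$epc_iters,
                     epsilon = config$epsilon_dmnc, seed = seeds[["network"]]),
    k = config$hub_topk, min_degree = config$min_degree_keep)
  results$ddgs <- ddgs
  results$hub_table <- hubs
  say("network", t0)

  t0 <- as.numeric(Sys.time())
  perm <- permutation_null(disc$datasets[[1]], ddgs$sets$ddg,
                           n_perm = config$n_perm, alpha = config$alpha_ssgsea,
                           seed = seeds[["permutation"]])
  results$permutation <- perm
  say("permutation", t0)

  t0 <- as.numeric(Sys.time())
  panel <- simulate_panel_cohort(signature_genes = ddgs$sets$ddg,
                                 seed = seeds[["panel"]])
  profile <- build_correlation_profile(panel$datasets, ddgs$sets$ddg,
                                       alpha = config$alpha_ssgsea,
                                       max_missing = config$max_missing_genes,
                                       panel_genes = unlist(panel$truth$blocks,
                                                            use.names = FALSE))
  ddc <- kmeans_cluster(profile, k = config$k_clusters,
                        seed = seeds[["kmeans"]],
                        n_restarts = config$kmeans_restarts)
  results$panel_truth <- panel$truth
  results$profile <- profile
  results$ddc <- ddc
  say("kmeans", t0)

  t0 <- as.numeric(Sys.time())
  resp <- simulate_response_cohort(blocks = panel$truth$blocks,
                                   seed = seeds[["response"]])
  valid <- simulate_response_cohort(blocks = panel$truth$blocks,
                                    reuse_truth = resp$truth,
                                    seed = seeds[["validation"]])
  rdegs <- moderated_t_test(resp$cohort, case_label = "non-responder",
                            control_label = "responder")
  rdegs_sig <- dplyr::filter(rdegs, .data$q < config$alpha_bh)
  overlap <- response_deg_overlap(rdegs_sig, ddc,
                                  logfc_threshold = config$logfc_threshold_response)
  models <- run_per_cluster_models(resp$cohort, valid$cohort, ddc,
                                   config = ln_config_with_seed(config, seeds[["models"]]))
  results$response_truth <- resp$truth
  results$response_n <- ncol(resp$cohort$values)
  results$response_degs <- rdegs
  results$overlap <- overlap
  results$models <- models
  top <- models$selected_genes[[1]]
  if (length(top) >= 4) {
    top_cluster_genes <- tidy(ddc)$gene[tidy(ddc)$cluster == models$cluster[1]]
    subnet <- simulate_network(node_names = top_cluster_genes,
                               planted_members = list(top),
                               background_p = 0.05,
                               seed = spawn_seed(seeds[["models"]], 99))
    results$top_regulatory <- suppressWarnings(
      rank_selected_genes(subnet$network, top, k = config$hub_topk,
                          seed = seeds[["models"]],
                          response_degs = rdegs_sig$gene,
                          epc_iters = config$epc_iters,
                          epsilon = config$epsilon_dmnc))
  }
  say("models", t0)

  # write plain-text stage outputs and digest them
  files <- character()
  wr <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
  }
  for (nm in names(degs))
    wr(degs[[nm]], sprintf("deg_%s.tsv", nm), function(o, p) readr::write_tsv(o, p, progress = FALSE))
  wr(ddgs, "ddg_signature.gmt", write_gmt)
  wr(hubs, "hub_table.tsv", function(o, p) readr::write_tsv(o, p, progress = FALSE))
  wr(glance(perm), "permutation.json",
     function(o, p) jsonlite::write_json(as.list(o), p, auto_unbox = TRUE, digits = NA))
  wr(as_tibble(profile), "correlation_profile.tsv",
     function(o, p) readr::write_tsv(o, p, progress = FALSE))
  wr(tidy(ddc), "ddc_assignment.tsv", function(o, p) readr::write_tsv(o, p, progress = FALSE))
  if (!is.null(ddc$wss_curve))
    wr(ddc$wss_curve, "wss_curve.csv", function(o, p) readr::write_csv(o, p, progress = FALSE))
  wr(overlap, "response_overlap.tsv", function(o, p) readr::write_tsv(o, p, progress = FALSE))
  wr(dplyr::select(models, -"selected_genes"), "model_summary.csv",
     function(o, p) readr::write_csv(o, p, progress = FALSE))
  digests <- tools::md5sum(files)
  names(digests) <- basename(names(digests))

  manifest <- structure(list(
    config = unclass(config),
    seeds = as.list(seeds),
    digests = as.list(digests),
    out_dir = out_dir,
    results = results,
    version = as.character(utils::packageVersion("lnflare"))
  ), class = "pipeline_manifest")
  jsonlite::write_json(manifest[c("config", "seeds", "digests", "version")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

ln_config_with_seed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> v%s, master seed %d\n", x$version,
              x$config$seed))
  cat(sprintf("  %d output file(s) under %s\n", length(x$digests), x$out_dir))
  invisible(x)
}
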