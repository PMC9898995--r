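#' Synthetic ground truth
#'
#' Every generator returns, alongside its data, a `synthetic_truth` list
#' recording exactly what was planted (differentially expressed genes with
#' effect sizes, hub-program genes, network modules, panel correlation blocks,
#' predictive genes with their logistic coefficients), so every downstream
#' stage can be checked mechanically against ground truth.
#'
#' @name synthetic_truth
NULL

new_truth <- function(...) structure(list(...), class = "synthetic_truth")

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.atomic(v)) paste0(class(v)[1], "[", length(v), "]")
                else paste0(class(v)[1], " (", length(v), ")")))
  }
  invisible(x)
}

#' Simulate case/control discovery datasets with a shared DEG program
#'
#' Emulates multi-compartment discovery cohorts: per-gene baselines are drawn
#' once and shared across datasets; planted up/down genes are shifted by
#' `+/-effect_size` (log2 units) in cases in every dataset; a latent
#' "hub program" activity (Gaussian, mean-shifted upward by `effect_size`
#' in cases) additively drives the planted hub genes, so hub genes are both
#' up-regulated and mutually correlated. All remaining genes are pure noise.
#'
#' @param n_datasets Number of datasets/compartments.
#' @param n_genes Genes per dataset (>= 50).
#' @param n_case,n_control Samples per group (labels `"LN"` / `"control"`).
#' @param effect_size Planted shift in log2 units (> 0 unless simulating a
#'   null; 0 is allowed and plants nothing detectable).
#' @param noise_sd Residual Gaussian noise SD.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes.
#' @param n_hub Number of hub-program genes (a subset of the up genes).
#' @param n_hub_down Number of down-module genes (a subset of the down genes),
#'   recorded as the planted down-regulated network module.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `datasets` (list of [expression_matrix()]) and `truth`
#'   ([synthetic_truth]).
#' @export
simulate_discovery_datasets <- function(n_datasets = 3, n_genes = 2000,
                                        n_case = 30, n_control = 30,
                                        effect_size = 2, noise_sd = 0.5,
                                        n_up = 60, n_down = 20,
                                        n_hub = 40, n_hub_down = 7,
                                        seed = 1) {
  if (n_genes < 50) ln_stop("n_genes must be >= 50")
  if (effect_size < 0) ln_stop("effect_size must be >= 0")
  if (n_case < 1 || n_control < 1) ln_stop("sample counts must be positive")
  if (n_up + n_down > n_genes %/% 2) ln_stop("too many planted genes for n_genes")
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    planted <- sample(genes, n_up + n_down)
    up <- planted[seq_len(n_up)]
    down <- planted[n_up + seq_len(n_down)]
    hub <- up[seq_len(min(n_hub, n_up))]
    hub_down <- down[seq_len(min(n_hub_down, n_down))]
    mu <- stats::rnorm(n_genes, mean = 7, sd = 1)
    names(mu) <- genes
    # heterogeneous per-gene effects (shared across datasets): the common
    # program has a spectrum of fold changes, not one value
    up_eff <- effect_size * stats::runif(n_up, 0.5, 1.5)
    dn_eff <- -effect_size * stats::runif(n_down, 0.5, 1.5)
    hub_load <- stats::runif(length(hub), 0.5, 1.5)
    shift <- stats::setNames(numeric(n_genes), genes)
    shift[up] <- up_eff
    shift[hub] <- 0  # hub genes are driven by the latent activity instead
    shift[down] <- dn_eff
    datasets <- lapply(seq_len(n_datasets), function(d) {
      n <- n_case + n_control
      case <- c(rep(1, n_case), rep(0, n_control))
      samples <- sprintf("D%d_S%02d", d, seq_len(n))
      # latent hub-program activity, higher in cases
      act <- stats::rnorm(n) + effect_size * case
      vals <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n,
                     dimnames = list(genes, samples))
      vals <- vals + mu + outer(shift, case)
      vals[hub, ] <- vals[hub, ] + outer(hub_load, act)
      labels <- stats::setNames(ifelse(case == 1, "LN", "control"), samples)
      expression_matrix(vals, labels, dataset_id = sprintf("discovery%d", d),
                        compartment = c("glomeruli", "tubulointerstitium",
                                        "kidney")[(d - 1) %% 3 + 1])
    })
    up_truth_eff <- up_eff
    up_truth_eff[match(hub, up)] <- hub_load * effect_size
    truth <- new_truth(
      planted_degs_up = tibble(gene = up, effect = up_truth_eff),
      planted_degs_down = tibble(gene = down, effect = dn_eff),
      planted_hub_genes = hub,
      planted_hub_genes_down = hub_down,
      effect_size = effect_size, noise_sd = noise_sd
    )
    list(datasets = datasets, truth = truth)
  })
}

#' Simulate an immunology-panel cohort with planted correlation blocks
#'
#' Emulates a targeted ~500-gene immunology panel measured across several
#' datasets/compartments. Each dataset carries (i) the signature genes, driven
#' strongly by a latent per-sample activity so their ssGSEA score tracks the
#' latent factor, (ii) background genes (pure noise, completing the scoring
#' universe), and (iii) panel genes partitioned into blocks, where a gene in
#' block *b* has population correlation `block_rho[b]` with the latent
#' activity. Optionally one dataset is generated with signature genes removed,
#' to exercise the missing-gene dataset-exclusion rule.
#'
#' @param n_panel_genes Number of panel genes (partitioned evenly into blocks).
#' @param n_blocks Number of correlation blocks (>= 2).
#' @param n_samples_per_dataset Integer vector, samples per dataset; its
#'   length sets the number of datasets.
#' @param block_rho Target correlation per block (recycled/truncated to
#'   `n_blocks`), each in (-1, 1).
#' @param signature_genes Gene symbols for the signature; default invents
#'   `SIG001..SIG040`.
#' @param n_background Background (non-signature, non-panel) genes.
#' @param signature_loading Latent-activity loading of signature genes.
#' @param noise_sd Residual noise SD for signature genes.
#' @param missing_in_dataset Index of a dataset to generate with missing
#'   signature genes (`NULL` for none).
#' @param n_missing How many signature genes to drop there.
#' @param seed Integer seed.
#' @return A list with `datasets` (list of [expression_matrix()], compartment
#'   `"panel"`) and `truth` with `blocks` (named list block id -> panel genes)
#'   and `block_rho`.
#' @export
simulate_panel_cohort <- function(n_panel_genes = 500, n_blocks = 8,
                                  n_samples_per_dataset = rep(100, 5),
                                  block_rho = c(0.8, 0.6, 0.4, 0.2, 0,
                                                -0.4, -0.6, -0.8),
                                  signature_genes = NULL,
                                  n_background = 200,
                                  signature_loading = 1, noise_sd = 0.5,
                                  missing_in_dataset = NULL, n_missing = 0,
                                  seed = 1) {
  if (n_blocks < 2) ln_stop("n_blocks must be >= 2")
  if (any(abs(block_rho) >= 1)) ln_stop("block_rho values must lie in (-1, 1)")
  block_rho <- rep_len(block_rho, n_blocks)
  signature_genes <- signature_genes %||% sprintf("SIG%03d", 1:40)
  block_id <- sort(rep_len(seq_len(n_blocks), n_panel_genes))
  if (min(table(block_id)) < 2) ln_stop("block sizes must be >= 2")
  panel_genes <- sprintf("PNL%03d", seq_len(n_panel_genes))
  blocks <- split(panel_genes, sprintf("B%d", block_id))
  bg_genes <- if (n_background > 0) sprintf("BKG%03d", seq_len(n_background)) else character()
  with_seed(seed, {
    compartments <- rep_len(c("glomeruli", "tubulointerstitium", "kidney",
                              "blood", "blood"), length(n_samples_per_dataset))
    datasets <- lapply(seq_along(n_samples_per_dataset), function(d) {
      n <- n_samples_per_dataset[d]
      samples <- sprintf("P%d_S%03d", d, seq_len(n))
      act <- stats::rnorm(n)
      sig <- 7 + signature_loading * matrix(act, length(signature_genes), n,
                                            byrow = TRUE) +
        matrix(stats::rnorm(length(signature_genes) * n, sd = noise_sd),
               length(signature_genes), n)
      rho_g <- block_rho[block_id]
      pan <- 7 + outer(rho_g, act) +
        matrix(stats::rnorm(n_panel_genes * n), n_panel_genes, n) *
        sqrt(1 - rho_g^2)
      bg <- matrix(stats::rnorm(length(bg_genes) * n, mean = 7), length(bg_genes), n)
      vals <- rbind(sig, pan, bg)
      rownames(vals) <- c(signature_genes, panel_genes, bg_genes)
      colnames(vals) <- samples
      if (!is.null(missing_in_dataset) && d == missing_in_dataset && n_missing > 0)
        vals <- vals[setdiff(rownames(vals),
                             signature_genes[seq_len(min(n_missing, length(signature_genes)))]),
                     , drop = FALSE]
      expression_matrix(vals, stats::setNames(rep("LN", n), samples),
                        dataset_id = sprintf("panel%d", d),
                        compartment = compartments[d])
    })
    truth <- new_truth(blocks = blocks,
                       block_rho = stats::setNames(block_rho, names(blocks)),
                       signature_genes = signature_genes)
    list(datasets = datasets, truth = truth)
  })
}

#' Simulate a response-labeled flare cohort with planted predictive genes
#'
#' Emulates a treatment-response cohort on the immunology panel: panel genes
#' keep their block membership, but each block is driven by its own
#' independent per-patient factor (within-block correlation `within_rho`),
#' and responder labels follow a logistic model whose non-zero coefficients
#' live only on `n_predictive` genes inside one block. The intercept is tuned
#' by root finding so the marginal responder:non-responder ratio approximates
#' `imbalance`; a majority `frac_up_nonresponder` of the planted effects is
#' oriented so higher expression predicts non-response.
#'
#' @param blocks Named list block id -> panel genes (e.g. from
#'   [simulate_panel_cohort()] truth); `NULL` builds the default 8-block,
#'   500-gene panel.
#' @param n_patients Cohort size.
#' @param imbalance Target responder:non-responder ratio (> 1).
#' @param predictive_block Block id holding all predictive genes.
#' @param n_predictive Number of predictive genes.
#' @param coef_scale Absolute logistic coefficient per predictive gene (on the
#'   standardized expression scale); 0 gives a label-independent null cohort.
#' @param frac_up_nonresponder Fraction of predictive effects oriented
#'   up-in-non-responders.
#' @param within_rho Within-block correlation of panel genes.
#' @param gene_sd Per-gene expression SD in log2 units (typical for a
#'   normalized targeted panel); sets the scale of induced fold changes.
#' @param reuse_truth Optional truth from a previous call: reuses its planted
#'   predictive genes and coefficients (for generating an external validation
#'   cohort under the same response mechanism).
#' @param seed Integer seed.
#' @return A list with `cohort` (an [expression_matrix()], labels
#'   `"responder"`/`"non-responder"`) and `truth` with
#'   `planted_predictive_genes` (tibble gene/coefficient) and
#'   `block_of_predictive_genes`.
#' @export
simulate_response_cohort <- function(blocks = NULL, n_patients = 200,
                                     imbalance = 2.76,
                                     predictive_block = "B6",
                                     n_predictive = 5, coef_scale = 2,
                                     frac_up_nonresponder = 0.889,
                                     within_rho = 0.3, gene_sd = 2,
                                     reuse_truth = NULL, seed = 1) {
  if (imbalance <= 1) ln_stop("imbalance must be > 1 (responders are the majority)")
  if (is.null(blocks)) {
    ngene <- 500
    bid <- sort(rep_len(1:8, ngene))
    blocks <- split(sprintf("PNL%03d", seq_len(ngene)), sprintf("B%d", bid))
  }
  if (!predictive_block %in% names(blocks))
    ln_stop("predictive_block '%s' not among blocks", predictive_block)
  if (n_predictive > length(blocks[[predictive_block]]))
    ln_stop("n_predictive exceeds the size of block %s", predictive_block)
  genes <- unlist(blocks, use.names = FALSE)
  block_of <- rep(names(blocks), lengths(blocks))
  with_seed(seed, {
    samples <- sprintf("R_S%03d", seq_len(n_patients))
    vals <- matrix(NA_real_, length(genes), n_patients,
                   dimnames = list(genes, samples))
    for (b in names(blocks)) {
      f <- stats::rnorm(n_patients)
      idx <- block_of == b
      vals[idx, ] <- 7 + gene_sd *
        (sqrt(within_rho) * matrix(f, sum(idx), n_patients, byrow = TRUE) +
           sqrt(1 - within_rho) * matrix(stats::rnorm(sum(idx) * n_patients),
                                         sum(idx), n_patients))
    }
    if (!is.null(reuse_truth)) {
      pred <- reuse_truth$planted_predictive_genes$gene
      coefs <- reuse_truth$planted_predictive_genes$coefficient
      predictive_block <- reuse_truth$block_of_predictive_genes
      coef_scale <- max(abs(coefs))
    } else {
      pred <- sample(blocks[[predictive_block]], n_predictive)
      n_dn <- round(frac_up_nonresponder * n_predictive)
      # negative sign w.r.t. responder odds = up-regulated in non-responders
      coefs <- coef_scale * c(rep(-1, n_dn), rep(1, n_predictive - n_dn))
    }
    eta0 <- if (coef_scale > 0)
      drop(scale(t(vals[pred, , drop = FALSE])) %*% coefs)
    else rep(0, n_patients)
    p_target <- imbalance / (1 + imbalance)
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) - p_target,
                         c(-30, 30))$root
    pr <- stats::plogis(b0 + eta0)
    labels <- NULL
    for (attempt in seq_len(100)) {
      y <- stats::rbinom(n_patients, 1, pr)
      if (length(unique(y)) == 2) { labels <- y; break }
      ln_warn("degenerate single-class label draw; resampling (attempt %d)", attempt)
    }
    if (is.null(labels)) ln_stop("could not draw a two-class cohort in 100 attempts")
    labels <- stats::setNames(ifelse(labels == 1, "responder", "non-responder"),
                              samples)
    cohort <- expression_matrix(vals, labels, dataset_id = "response_cohort",
                                compartment = "panel")
    truth <- new_truth(
      planted_predictive_genes = tibble(gene = pred, coefficient = coefs),
      block_of_predictive_genes = predictive_block,
      blocks = blocks, intercept = b0
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate an interaction network with planted dense modules
#'
#' Erdős–Rényi background with planted (near-)cliques on disjoint node sets;
#' ground truth records module membership. Used as the substrate for MCODE
#' module detection and hub centralities.
#'
#' @param n_nodes Number of nodes (ignored when `node_names` is given).
#' @param background_p Background edge probability in `[0, 0.2]`.
#' @param planted_clique_sizes Integer sizes (each >= 4) of planted modules,
#'   used when `planted_members` is `NULL`.
#' @param planted_members Optional list of explicit disjoint node sets to
#'   plant; overlapping sets are a hard error.
#' @param clique_edge_p Probability of each within-module edge (1 = exact
#'   clique).
#' @param node_names Optional node symbols.
#' @param seed Integer seed.
#' @return A list with `network` (igraph) and `truth` with `planted_modules`.
#' @export
simulate_network <- function(n_nodes = 200, background_p = 0.02,
                             planted_clique_sizes = c(8, 6),
                             planted_members = NULL, clique_edge_p = 1,
                             node_names = NULL, seed = 1) {
  if (background_p < 0 || background_p > 0.2)
    ln_stop("background_p must be in [0, 0.2]")
  nodes <- node_names %||% sprintf("N%03d", seq_len(n_nodes))
  n_nodes <- length(nodes)
  if (is.null(planted_members)) {
    if (length(planted_clique_sizes) && any(planted_clique_sizes < 4))
      ln_stop("planted clique sizes must be >= 4")
    if (sum(planted_clique_sizes) > n_nodes)
      ln_stop("planted cliques need more nodes than available")
  } else {
    all_m <- unlist(planted_members)
    if (anyDuplicated(all_m)) ln_stop("planted node sets overlap")
    if (!all(all_m %in% nodes)) ln_stop("planted members must be among the nodes")
  }
  with_seed(seed, {
    g <- igraph::sample_gnp(n_nodes, background_p, directed = FALSE)
    igraph::V(g)$name <- nodes
    if (is.null(planted_members)) {
      pool <- sample(nodes)
      planted_members <- list()
      off <- 0
      for (s in planted_clique_sizes) {
        planted_members[[length(planted_members) + 1]] <- pool[off + seq_len(s)]
        off <- off + s
      }
    }
    for (members in planted_members) {
      pairs <- utils::combn(members, 2)
      keep <- stats::runif(ncol(pairs)) <= clique_edge_p
      if (any(keep))
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
    }
    g <- igraph::simplify(g)
    truth <- new_truth(planted_modules = planted_members,
                       background_p = background_p)
    list(network = g, truth = truth)
  })
}
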