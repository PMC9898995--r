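#' Single-sample gene-set enrichment score
#'
#' Rank-based per-sample enrichment: genes are ordered by decreasing
#' expression (ties broken by gene symbol), the gene at position `pos` gets
#' rank `r = N - pos + 1`, and the score is the sum over all positions of
#' `P_in - P_out`, where `P_in` accumulates `r^alpha` over in-set genes
#' (normalized by the in-set total) and `P_out` accumulates `1/(N - m)` over
#' out-of-set genes (`m` = in-set size). Equivalently, in closed form,
#' `score = sum_in r^(1+alpha) / sum_in r^alpha  -  sum_out r / (N - m)`.
#' The score depends on the expression values only through their ranks.
#'
#' @param sample_expression Named numeric vector, gene -> expression.
#' @param gene_set Character vector of gene symbols; its intersection with
#'   the measured genes must be non-empty and a proper subset of them.
#' @param alpha Rank-weight exponent (canonical value 0.25).
#' @return A single numeric score.
#' @export
ssgsea_score <- function(sample_expression, gene_set, alpha = 0.25) {
  genes <- names(sample_expression)
  if (is.null(genes)) ln_stop("`sample_expression` must be a named vector")
  in_set <- genes %in% gene_set
  m <- sum(in_set); n <- length(genes)
  if (m == 0) ln_stop("gene set shares no genes with the sample")
  if (m == n) ln_stop("gene set covers every measured gene; out-of-set walk undefined")
  r <- numeric(n)
  r[order(-sample_expression, genes)] <- n:1
  sum(r[in_set]^(1 + alpha)) / sum(r[in_set]^alpha) - sum(r[!in_set]) / (n - m)
}

# Per-sample descending ranks (ties by gene symbol) for a genes x samples
# matrix; shared by the matrix and permutation paths.
ssgsea_ranks <- function(values) {
  genes <- rownames(values)
  n <- nrow(values)
  apply(values, 2, function(x) {
    r <- numeric(n)
    r[order(-x, genes)] <- n:1
    r
  })
}

# Score many sets against precomputed ranks. `sets` is a list of integer
# index vectors into the gene rows.
score_sets_on_ranks <- function(ranks, set_idx, alpha) {
  n <- nrow(ranks)
  total <- colSums(ranks)
  vapply(set_idx, function(idx) {
    m <- length(idx)
    rs <- ranks[idx, , drop = FALSE]
    colSums(rs^(1 + alpha)) / colSums(rs^alpha) - (total - colSums(rs)) / (n - m)
  }, numeric(ncol(ranks)))
}

#' ssGSEA scores for a signature collection across all samples
#'
#' Applies [ssgsea_score()] per sample and per set. Genes absent from the
#' matrix are dropped from each set with a message; a set losing all its
#' genes is skipped with a warning.
#'
#' @param x An [expression_matrix()].
#' @param sets A [signature_collection()] or a named list of gene vectors.
#' @param alpha Rank-weight exponent.
#' @return A tibble with columns `set`, `sample`, `score`, `label`.
#' @export
ssgsea_matrix <- function(x, sets, alpha = 0.25) {
  if (inherits(sets, "signature_collection")) sets <- sets$sets
  genes <- em_genes(x)
  if (anyNA(x$values)) ln_stop("ssGSEA requires a complete matrix (no NAs)")
  ranks <- ssgsea_ranks(x$values)
  keep <- list()
  for (nm in names(sets)) {
    present <- intersect(sets[[nm]], genes)
    dropped <- length(sets[[nm]]) - length(present)
    if (dropped > 0)
      message(sprintf("set %s: %d gene(s) absent from the matrix", nm, dropped))
    if (length(present) == 0) {
      ln_warn("set %s has no genes in the matrix; skipped", nm)
      next
    }
    if (length(present) == length(genes)) {
      ln_warn("set %s covers every measured gene; skipped", nm)
      next
    }
    keep[[nm]] <- match(present, genes)
  }
  if (!length(keep))
    return(tibble(set = character(), sample = character(),
                  score = numeric(), label = character()))
  scores <- score_sets_on_ranks(ranks, keep, alpha)
  tibble(
    set = rep(names(keep), each = ncol(x$values)),
    sample = rep(em_samples(x), times = length(keep)),
    score = as.vector(scores),
    label = rep(unname(x$labels), times = length(keep))
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sided; exact enumeration when both groups have at most 8 observations
#' and there are no ties, normal approximation with tie correction otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A list with `statistic` (the rank-sum W for `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) ln_stop("both groups must be non-empty")
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = !exact))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Permutation null for a gene signature's ssGSEA case/control difference
#'
#' Computes the observed difference in mean ssGSEA score between cases and
#' controls (with a Wilcoxon rank-sum p-value), then builds a background of
#' `n_perm` random gene sets of the same size drawn uniformly without
#' replacement from the matrix's gene universe, scoring each the same way.
#' The empirical p-value uses the add-one convention
#' `(1 + #\{background >= observed\}) / (n_perm + 1)`.
#'
#' @param x An [expression_matrix()] with case/control labels.
#' @param signature Gene vector to test.
#' @param n_perm Number of random sets (>= 1).
#' @param alpha Rank-weight exponent.
#' @param seed Integer seed (background is deterministic given it).
#' @param case_label,control_label Group labels.
#' @return A `perm_report` list: `observed_mean_diff`, `observed_p`,
#'   `background` (tibble `mean_diff`, `p`), `empirical_p`, `n_perm`.
#' @export
permutation_null <- function(x, signature, n_perm = 1000, alpha = 0.25,
                             seed = 1, case_label = "LN",
                             control_label = "control") {
  if (n_perm < 1) ln_stop("n_perm must be >= 1")
  genes <- em_genes(x)
  present <- intersect(signature, genes)
  if (!length(present)) ln_stop("signature shares no genes with the matrix")
  if (length(present) == length(genes)) ln_stop("signature covers all genes")
  is_case <- x$labels == case_label
  is_ctrl <- x$labels == control_label
  if (!any(is_case) || !any(is_ctrl))
    ln_stop("both '%s' and '%s' labels must be present", case_label, control_label)
  ranks <- ssgsea_ranks(x$values)
  m <- length(present)
  score_one <- function(idx) drop(score_sets_on_ranks(ranks, list(idx), alpha))
  obs_scores <- score_one(match(present, genes))
  observed_diff <- mean(obs_scores[is_case]) - mean(obs_scores[is_ctrl])
  observed_p <- wilcoxon_rank_sum(obs_scores[is_case], obs_scores[is_ctrl])$p
  bg <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_perm), function(i) {
      idx <- sample.int(length(genes), m)
      sc <- score_one(idx)
      tibble(mean_diff = mean(sc[is_case]) - mean(sc[is_ctrl]),
             p = wilcoxon_rank_sum(sc[is_case], sc[is_ctrl])$p)
    })
  })
  structure(list(observed_mean_diff = observed_diff, observed_p = observed_p,
                 background = bg,
                 empirical_p = (1 + sum(bg$mean_diff >= observed_diff)) / (n_perm + 1),
                 n_perm = n_perm),
            class = "perm_report")
}

#' @export
print.perm_report <- function(x, ...) {
  cat(sprintf("<perm_report> observed mean diff %.4f (Wilcoxon p = %.3g); empirical p = %.4g over %d permutations\n",
              x$observed_mean_diff, x$observed_p, x$empirical_p, x$n_perm))
  invisible(x)
}

#' Signed -log10 p-value
#'
#' `-log10(p)` signed positive when the quantity is higher in cases,
#' negative otherwise; `p = 0` is capped at +/-308 with a warning.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param higher_in_case Logical (recycled).
#' @return Signed value(s).
#' @export
signed_logp <- function(p, higher_in_case) {
  if (anyNA(p) || any(p < 0 | p > 1)) ln_stop("p must lie in [0, 1]")
  sgn <- ifelse(rep_len(higher_in_case, length(p)), 1, -1)
  out <- numeric(length(p))
  zero <- p == 0
  if (any(zero)) {
    ln_warn("p = 0 capped at |308|")
    out[zero] <- 308 * sgn[zero]
  }
  out[!zero] <- -log10(p[!zero]) * sgn[!zero]
  out
}

#' Correlate immune-signature enrichment with a target gene
#'
#' Scores each immune-cell signature by ssGSEA across samples and reports
#' Spearman's rho between each score profile and the target gene's
#' expression — the immune-infiltration correlation for a candidate
#' regulatory gene.
#'
#' @param x An [expression_matrix()].
#' @param immune_sets A [signature_collection()] of immune-cell signatures.
#' @param target_gene Gene symbol present in the matrix.
#' @param alpha Rank-weight exponent.
#' @return A tibble `set`, `rho` (NA with a warning for a constant target).
#' @export
immune_correlation <- function(x, immune_sets, target_gene, alpha = 0.25) {
  if (!target_gene %in% em_genes(x))
    ln_stop("target gene '%s' not in the matrix", target_gene)
  target <- x$values[target_gene, ]
  scores <- ssgsea_matrix(x, immune_sets, alpha = alpha)
  if (stats::sd(target) == 0) {
    ln_warn("target gene '%s' has constant expression; rho undefined", target_gene)
    return(tibble(set = unique(scores$set),
                  rho = NA_real_))
  }
  wide <- tidyr::pivot_wider(scores[, c("set", "sample", "score")],
                             names_from = "sample", values_from = "score")
  tibble(
    set = wide$set,
    rho = apply(as.matrix(wide[, -1])[, em_samples(x), drop = FALSE], 1,
                function(s) stats::cor(s, target, method = "spearman"))
  )
}
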