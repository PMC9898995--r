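#' Empirical-Bayes moderated two-group differential expression
#'
#' Fits, per gene, the two-group contrast `case - control` and computes a
#' moderated t-statistic in which the pooled sample variance is shrunk toward
#' a prior variance. The prior degrees of freedom `d0` and prior variance
#' `s0^2` are estimated by method of moments on the log sample variances:
#' with `d` residual df and `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`,
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` (solved by Newton's method) and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The moderated variance
#' is `(d0*s0^2 + d*s^2)/(d0 + d)` and the statistic is referred to a t
#' distribution on `d + d0` df. With `prior_df = 0` the statistic reduces
#' exactly to the ordinary pooled-variance two-sample t.
#'
#' @param x An [expression_matrix()].
#' @param case_label,control_label Group labels to contrast (each needs >= 2
#'   samples).
#' @param prior_df `NULL` to estimate the prior df (default), `0` for the
#'   ordinary t, or a fixed non-negative value (`Inf` shrinks fully).
#' @return A tibble with one row per gene: `gene`, `logfc` (log2 case -
#'   control), `ave_expr`, `t_mod`, `p`, `q` (BH), `direction` (`"up"` for
#'   `logfc >= 0`, else `"down"`).
#' @export
moderated_t_test <- function(x, case_label, control_label, prior_df = NULL) {
  case <- names(x$labels)[x$labels == case_label]
  ctrl <- names(x$labels)[x$labels == control_label]
  if (length(case) < 2 || length(ctrl) < 2)
    ln_stop("need >= 2 samples per group (got %d '%s', %d '%s')",
            length(case), case_label, length(ctrl), control_label)
  v <- x$values
  if (anyNA(v)) ln_stop("expression matrix contains missing values")
  xc <- v[, case, drop = FALSE]; xt <- v[, ctrl, drop = FALSE]
  n1 <- length(case); n2 <- length(ctrl); d <- n1 + n2 - 2
  m1 <- rowMeans(xc); m2 <- rowMeans(xt)
  logfc <- m1 - m2
  s2 <- (rowSums((xc - m1)^2) + rowSums((xt - m2)^2)) / d
  if (any(s2 <= 0)) {
    floor_val <- if (any(s2 > 0)) min(s2[s2 > 0]) else 1e-8
    ln_warn("%d zero-variance gene(s); variance floored at %.3g",
            sum(s2 <= 0), floor_val)
    s2[s2 <= 0] <- floor_val
  }
  if (is.null(prior_df)) {
    mom <- fit_variance_prior(s2, d)
    d0 <- mom$df_prior; s02 <- mom$var_prior
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0  # unused when d0 = 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  tstat <- logfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  # total df capped at the pooled residual df across all genes
  df_tot <- min(d + d0, d * length(s2))
  p <- if (is.infinite(df_tot)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_tot)
  tibble(
    gene = rownames(v), logfc = unname(logfc),
    ave_expr = unname((m1 * n1 + m2 * n2) / (n1 + n2)),
    t_mod = unname(tstat), p = unname(p), q = bh_adjust(unname(p)),
    direction = ifelse(logfc >= 0, "up", "down")
  )
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior on the
# log scale (closed form via digamma/trigamma; Newton for the trigamma
# inverse).
fit_variance_prior <- function(s2, d) {
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  n <- length(e)
  evar <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(d / 2)
  # underdispersed log-variances: no Bayes shrinkage needed, the pooled mean
  # variance is the maximum-likelihood scale
  if (!is.finite(evar) || evar <= 0)
    return(list(df_prior = Inf, var_prior = mean(s2)))
  d0 <- 2 * trigamma_inverse(evar)
  list(df_prior = d0,
       var_prior = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
}

trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1 and order-preserving with the
#' input. Values outside `[0, 1]` are a hard error.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    ln_stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvals, method = "BH")
}

#' Multi-set DEG intersection (Venn summary)
#'
#' @param named_sets Named list (>= 2) of gene character vectors.
#' @return A `venn_summary` list: `set_sizes` (tibble), `pairwise` (tibble of
#'   pairwise intersection sizes), `regions` (tibble of exclusive-region
#'   counts keyed by the sets a gene belongs to), and `common` (the full
#'   intersection gene vector).
#' @export
intersect_deg_sets <- function(named_sets) {
  if (!length(named_sets)) ln_stop("need at least one gene set")
  if (length(named_sets) < 2) ln_stop("need >= 2 gene sets to intersect")
  if (is.null(names(named_sets)) || any(names(named_sets) == ""))
    ln_stop("gene sets must be named")
  named_sets <- lapply(named_sets, function(g) unique(as.character(g)))
  universe <- unique(unlist(named_sets))
  member <- vapply(named_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(named_sets)))
  sig <- apply(member, 1, function(row) paste(names(named_sets)[row], collapse = "&"))
  regions <- dplyr::count(tibble(region = sig), .data$region, name = "n")
  pairs <- utils::combn(names(named_sets), 2)
  pairwise <- tibble(
    set1 = pairs[1, ], set2 = pairs[2, ],
    n = apply(pairs, 2, function(p)
      length(intersect(named_sets[[p[1]]], named_sets[[p[2]]])))
  )
  common <- universe[rowSums(member) == ncol(member)]
  structure(list(
    set_sizes = tibble(set = names(named_sets), n = lengths(named_sets)),
    pairwise = pairwise, regions = regions, common = common
  ), class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("<venn_summary>\n  set sizes:",
      paste(sprintf("%s=%d", x$set_sizes$set, x$set_sizes$n), collapse = ", "),
      sprintf("\n  common genes: %d\n", length(x$common)))
  invisible(x)
}

#' Spearman concordance of log fold changes between two DEG tables
#'
#' @param a,b Tibbles as returned by [moderated_t_test()] (need `gene` and
#'   `logfc`); correlation is computed on the shared-gene intersection (>= 3
#'   genes).
#' @return Spearman's rho.
#' @export
logfc_concordance <- function(a, b) {
  shared <- dplyr::inner_join(a[, c("gene", "logfc")], b[, c("gene", "logfc")],
                              by = "gene", suffix = c("_a", "_b"))
  if (nrow(shared) < 3) ln_stop("need >= 3 shared genes (got %d)", nrow(shared))
  spearman_rho(shared$logfc_a, shared$logfc_b)
}

#' Flag samples whose label contradicts their expression cluster
#'
#' Clusters samples on the expression of the supplied DEG genes
#' (average-linkage hierarchical clustering, 1 - Pearson correlation
#' distance), cuts the tree into two clusters, assigns each cluster its
#' majority label, and returns the samples whose label contradicts their
#' cluster's majority — the label-inconsistent samples removed before
#' building unbiased discovery sets.
#'
#' @param x An [expression_matrix()] with exactly two label values.
#' @param deg_genes Gene set to cluster on (>= 10 present in the matrix).
#' @return Character vector of flagged sample ids (possibly empty). A warning
#'   is emitted when the two clusters share a majority label (no consistent
#'   binary structure; empty return) or when more than a quarter of samples
#'   are flagged (labels look shuffled).
#' @export
flag_mislabeled_samples <- function(x, deg_genes) {
  genes <- intersect(deg_genes, em_genes(x))
  if (length(genes) < 10)
    ln_stop("need >= 10 DEG genes present in the matrix (got %d)", length(genes))
  if (length(unique(x$labels)) != 2)
    ln_stop("expected exactly two label values")
  v <- x$values[genes, , drop = FALSE]
  dmat <- stats::as.dist(1 - stats::cor(v))
  cl <- stats::cutree(stats::hclust(dmat, method = "average"), k = 2)
  maj <- vapply(1:2, function(k) {
    names(which.max(table(x$labels[names(cl)[cl == k]])))
  }, character(1))
  if (maj[1] == maj[2]) {
    ln_warn("both sample clusters share majority label '%s'; no samples flagged", maj[1])
    return(character())
  }
  flagged <- names(cl)[x$labels[names(cl)] != maj[cl]]
  if (length(flagged) > 0.25 * ncol(v))
    ln_warn("%d of %d samples contradict their cluster majority; labels may be shuffled",
            length(flagged), ncol(v))
  flagged
}
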