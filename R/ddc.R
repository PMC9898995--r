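#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Constant
#' vectors are a hard error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) ln_stop("x and y must have equal length")
  if (length(x) < 3) ln_stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ln_stop("constant vector: Spearman's rho undefined")
  stats::cor(x, y, method = "spearman")
}

#' Pooled correlation profile of panel genes against DDG activity
#'
#' For each dataset: computes the per-sample ssGSEA score of the DDG
#' signature, then Spearman's rho between that score and each panel gene's
#' expression across the dataset's samples. Datasets missing more than
#' `max_missing` signature genes are excluded with a recorded reason
#' (the missing-gene exclusion rule). Profile columns (one per retained
#' dataset) are pooled side by side; panel genes absent from some retained
#' dataset carry `NA` entries there (mean-imputed at clustering time).
#'
#' @param panel_sets List of [expression_matrix()] panel datasets (each with
#'   >= 4 samples).
#' @param signature Character vector, the DDG signature genes.
#' @param alpha ssGSEA rank-weight exponent.
#' @param max_missing Exclusion threshold on missing signature genes.
#' @param panel_genes Panel gene universe for the profile rows; defaults to
#'   all genes observed across datasets that are not signature genes.
#' @return A tibble of class `ddc_profile`: `gene` plus one rho column per
#'   retained dataset, with attribute `excluded` (tibble `dataset`,
#'   `reason`).
#' @export
build_correlation_profile <- function(panel_sets, signature, alpha = 0.25,
                                      max_missing = 5, panel_genes = NULL) {
  if (!length(panel_sets)) ln_stop("need >= 1 panel dataset")
  panel_genes <- panel_genes %||%
    setdiff(unique(unlist(lapply(panel_sets, em_genes))), signature)
  excluded <- tibble(dataset = character(), reason = character())
  cols <- list()
  for (em in panel_sets) {
    if (ncol(em$values) < 4)
      ln_stop("dataset %s has fewer than 4 samples", em$dataset_id)
    n_missing <- length(setdiff(signature, em_genes(em)))
    if (n_missing > max_missing) {
      excluded <- dplyr::bind_rows(excluded, tibble(
        dataset = em$dataset_id,
        reason = sprintf("%d missing signature genes (max %d)", n_missing, max_missing)))
      next
    }
    present_sig <- intersect(signature, em_genes(em))
    score <- ssgsea_matrix(em, list(sig = present_sig), alpha = alpha)$score
    pg <- intersect(panel_genes, em_genes(em))
    rho <- suppressWarnings(
      stats::cor(t(em$values[pg, , drop = FALSE]), score, method = "spearman"))
    col <- rep(NA_real_, length(panel_genes))
    names(col) <- panel_genes
    col[pg] <- drop(rho)
    cols[[em$dataset_id]] <- col
  }
  if (!length(cols)) ln_stop("all datasets excluded by the missing-gene rule")
  profile <- tibble(gene = panel_genes)
  for (nm in names(cols)) profile[[nm]] <- unname(cols[[nm]])
  attr(profile, "excluded") <- excluded
  class(profile) <- c("ddc_profile", class(profile))
  profile
}

profile_matrix <- function(profile) {
  m <- as.matrix(profile[, setdiff(names(profile), "gene"), drop = FALSE])
  rownames(m) <- profile$gene
  # row-mean imputation of missing correlations
  if (anyNA(m)) {
    rm <- rowMeans(m, na.rm = TRUE)
    bad <- which(!is.finite(rm))
    if (length(bad)) ln_stop("gene(s) with no finite correlation in any dataset: %s",
                             paste(rownames(m)[utils::head(bad, 5)], collapse = ", "))
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rm[idx[, 1]]
  }
  m
}

#' K-means disease-defining clusters of the correlation profile
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_restarts` by total
#' within-cluster sum of squares (WSS), deterministic given `seed`. With
#' `k = "auto"`, the WSS curve over `k_range` is computed and the
#' second-elbow rule ([elbow_select()]) picks k. The WSS curve is made
#' non-increasing by construction: each k+1 fit also tries a warm start that
#' splits the previous best solution.
#'
#' @param profile A `ddc_profile` (missing entries are row-mean imputed).
#' @param k Number of clusters (>= 2, <= number of genes) or `"auto"`.
#' @param seed Integer seed.
#' @param n_restarts Random restarts per k.
#' @param k_range Candidate k values for `k = "auto"` (consecutive).
#' @param which_elbow Elbow order for `k = "auto"`.
#' @return A `ddc_model` list: `k`, `assignment` (named integer gene ->
#'   cluster), `centers`, `tot_wss`, `wss_curve` (tibble `k`, `wss`),
#'   `chosen_k`, `seed`.
#' @export
kmeans_cluster <- function(profile, k = 8, seed = 1, n_restarts = 25,
                           k_range = 2:15, which_elbow = 2) {
  m <- profile_matrix(profile)
  auto <- identical(k, "auto")
  if (auto) {
    curve <- wss_curve(m, k_range = k_range, seed = seed, n_restarts = n_restarts)
    k <- elbow_select(curve, which_elbow = which_elbow)
  } else {
    if (k < 2) ln_stop("k must be >= 2")
    if (k > nrow(m)) ln_stop("k exceeds the number of profiled genes")
    curve <- NULL
  }
  fit <- kmeans_best(m, k, seed = seed, n_restarts = n_restarts)
  structure(list(
    k = k,
    assignment = stats::setNames(fit$cluster, rownames(m)),
    centers = fit$centers,
    tot_wss = fit$tot.withinss,
    wss_curve = curve,
    chosen_k = k,
    seed = seed
  ), class = "ddc_model")
}

#' @export
print.ddc_model <- function(x, ...) {
  cat(sprintf("<ddc_model> k = %d over %d genes; total WSS = %.2f\n",
              x$k, length(x$assignment), x$tot_wss))
  print(table(cluster = x$assignment))
  invisible(x)
}

# Best-of-restarts Lloyd k-means with k-means++ seeding; optional extra
# warm-start inits guarantee monotone WSS curves when called with increasing
# k (see wss_curve).
kmeans_best <- function(m, k, seed, n_restarts, extra_inits = list()) {
  if (k >= nrow(m)) {
    # one gene per cluster (or more clusters than rows is an error upstream)
    fit <- list(cluster = seq_len(nrow(m)), centers = m, tot.withinss = 0)
    return(fit)
  }
  best <- NULL
  with_seed(seed, {
    inits <- c(extra_inits,
               lapply(seq_len(n_restarts), function(i) kmeanspp_init(m, k)))
    for (init in inits) {
      fit <- NULL
      for (attempt in 1:20) {
        fit <- tryCatch(
          stats::kmeans(m, centers = init, iter.max = 100, algorithm = "Lloyd"),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit)) break
        init <- kmeanspp_init(m, k)  # re-seed on empty-cluster failure
      }
      if (is.null(fit)) ln_stop("k-means failed to converge without empty clusters in 20 attempts")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  best
}

kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  centers[1, ] <- m[sample.int(n, 1), ]
  d2 <- rowSums((m - matrix(centers[1, ], n, ncol(m), byrow = TRUE))^2)
  for (j in 2:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- m[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums((m - matrix(centers[j, ], n, ncol(m), byrow = TRUE))^2))
  }
  # jitter exact duplicates so stats::kmeans accepts the centers
  if (anyDuplicated(round(centers, 12)))
    centers <- centers + stats::rnorm(length(centers), sd = 1e-9)
  centers
}

#' Total within-cluster sum of squares over a range of k
#'
#' @param x A `ddc_profile` or numeric matrix of observations.
#' @param k_range Consecutive candidate k values.
#' @param seed,n_restarts As in [kmeans_cluster()].
#' @return A tibble `k`, `wss` (non-increasing in k).
#' @export
wss_curve <- function(x, k_range = 2:15, seed = 1, n_restarts = 25) {
  m <- if (is.matrix(x)) x else profile_matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range <= nrow(m)]
  wss <- numeric(length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    extra <- list()
    if (!is.null(prev) && nrow(prev$centers) == k - 1 && k <= nrow(m)) {
      # warm start: split the previous solution at its farthest point
      far <- which.max(rowSums((m - prev$centers[prev$cluster, , drop = FALSE])^2))
      extra <- list(rbind(prev$centers, m[far, ] + 1e-9))
    }
    fit <- kmeans_best(m, k, seed = spawn_seed(seed, k), n_restarts = n_restarts,
                       extra_inits = extra)
    wss[i] <- fit$tot.withinss
    prev <- fit
  }
  tibble(k = k_range, wss = wss)
}

#' Elbow selection on a WSS curve
#'
#' Elbows are the local maxima of the discrete second difference
#' `WSS(k-1) + WSS(k+1) - 2 WSS(k)` (curvature of the decreasing curve);
#' the function returns the `which_elbow`-th elbow in increasing k. If fewer
#' elbows exist, the last one is returned with a warning. A curve that is not
#' non-increasing is a hard error (it indicates an upstream k-means defect).
#'
#' @param curve A tibble with columns `k` and `wss` (consecutive k, length
#'   >= 5) or a named numeric vector (names = k).
#' @param which_elbow Which elbow to return (>= 1).
#' @return The selected k.
#' @export
elbow_select <- function(curve, which_elbow = 2) {
  if (is.numeric(curve) && !is.null(names(curve)))
    curve <- tibble(k = as.integer(names(curve)), wss = unname(curve))
  if (which_elbow < 1) ln_stop("which_elbow must be >= 1")
  k <- curve$k; wss <- curve$wss
  if (length(k) < 5) ln_stop("WSS curve must cover >= 5 consecutive k values")
  if (any(diff(k) != 1)) ln_stop("WSS curve must be over consecutive k values")
  if (any(diff(wss) > 1e-8 * max(abs(wss))))
    ln_stop("WSS curve is not non-increasing; upstream k-means defect")
  d2 <- wss[1:(length(wss) - 2)] + wss[3:length(wss)] - 2 * wss[2:(length(wss) - 1)]
  interior <- k[2:(length(k) - 1)]
  is_elbow <- vapply(seq_along(d2), function(i) {
    left_ok <- i == 1 || d2[i] > d2[i - 1]
    right_ok <- i == length(d2) || d2[i] >= d2[i + 1]
    left_ok && right_ok
  }, logical(1))
  elbows <- interior[is_elbow]
  if (!length(elbows)) ln_stop("no elbow found on the WSS curve")
  if (which_elbow > length(elbows)) {
    ln_warn("only %d elbow(s) found; returning the last", length(elbows))
    which_elbow <- length(elbows)
  }
  elbows[which_elbow]
}

#' @rdname tidy.expr_matrix
#' @export
tidy.ddc_model <- function(x, ...) {
  tibble(gene = names(x$assignment),
         cluster = sprintf("DDC-%d", unname(x$assignment)))
}

#' @rdname glance.perm_report
#' @export
glance.ddc_model <- function(x, ...) {
  tibble(k = x$k, n_genes = length(x$assignment), tot_wss = x$tot_wss,
         seed = x$seed)
}
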