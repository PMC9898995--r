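#' Distribution of response DEGs across disease-defining clusters
#'
#' For DEGs between responders and non-responders passing the |logFC|
#' threshold, reports per cluster the share of those DEGs falling in the
#' cluster and, within the cluster, the fraction whose fold change points
#' "up". Compute the DEG table with the non-responder group as the case so
#' that `"up"` reads as up-regulated in non-responders.
#'
#' @param response_degs Tibble from [moderated_t_test()] (columns `gene`,
#'   `logfc`, `direction`), already restricted to significant genes if
#'   desired.
#' @param ddc A `ddc_model` (or a tibble `gene`, `cluster`).
#' @param logfc_threshold Absolute log2 fold-change threshold (default 1).
#' @return A tibble `cluster`, `n_degs`, `frac_degs`, `frac_up` covering
#'   every cluster (zeros where no DEG falls). All-zero with a warning when
#'   no DEG passes the threshold.
#' @export
response_deg_overlap <- function(response_degs, ddc, logfc_threshold = 1) {
  assignment <- if (inherits(ddc, "ddc_model")) tidy(ddc) else ddc
  passing <- dplyr::filter(response_degs, abs(.data$logfc) >= logfc_threshold)
  clusters <- sort(unique(assignment$cluster))
  if (!nrow(passing)) {
    ln_warn("no DEG passes |logFC| >= %g", logfc_threshold)
    return(tibble(cluster = clusters, n_degs = 0L, frac_degs = 0, frac_up = 0))
  }
  hits <- dplyr::inner_join(passing, assignment, by = "gene")
  total <- nrow(hits)
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$cluster),
    n_degs = dplyr::n(),
    frac_up = mean(.data$direction == "up"),
    .groups = "drop")
  out <- dplyr::left_join(tibble(cluster = clusters), out, by = "cluster")
  out$n_degs[is.na(out$n_degs)] <- 0L
  out$frac_up[is.na(out$frac_up)] <- 0
  out$frac_degs <- if (total > 0) out$n_degs / total else 0
  out[, c("cluster", "n_degs", "frac_degs", "frac_up")]
}

#' Stratified train/test split of a response cohort
#'
#' Random split preserving class proportions (deterministic given `seed`).
#' Each class contributes `round(ratio * n_class)` samples to training; both
#' classes must appear in both partitions.
#'
#' @param cohort An [expression_matrix()] with binary labels and >= 5
#'   samples per class.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list `train`, `test` of [expression_matrix()] objects.
#' @export
split_train_test <- function(cohort, ratio = 0.8, seed = 1) {
  if (!(ratio > 0 && ratio < 1)) ln_stop("ratio must be in (0, 1)")
  classes <- split(names(cohort$labels), cohort$labels)
  if (length(classes) != 2) ln_stop("cohort must have exactly two classes")
  if (any(lengths(classes) < 5))
    ln_stop("need >= 5 samples per class (got %s)",
            paste(lengths(classes), collapse = "/"))
  with_seed(seed, {
    train_ids <- unlist(lapply(classes, function(ids) {
      n_tr <- round(ratio * length(ids))
      if (n_tr < 1 || n_tr >= length(ids))
        ln_stop("ratio %.2f leaves a class absent from the train or test split", ratio)
      sample(ids, n_tr)
    }), use.names = FALSE)
  })
  test_ids <- setdiff(names(cohort$labels), train_ids)
  list(train = em_subset(cohort, samples = train_ids),
       test = em_subset(cohort, samples = test_ids))
}

#' SMOTE minority oversampling
#'
#' Chawla-style synthetic minority oversampling: each synthetic sample
#' interpolates between a random minority sample and one of its `k` nearest
#' minority neighbours (Euclidean) with a single `u ~ U(0,1)` per synthetic
#' vector, until the classes are balanced 1:1 (within one sample).
#' Deterministic given `seed`.
#'
#' @param features Numeric matrix, samples in rows, genes in columns.
#' @param labels Character/factor vector of two classes, aligned with rows.
#' @param k Nearest-neighbour count; reduced with a warning when the
#'   minority class has `<= k` members (hard error below 2).
#' @param seed Integer seed.
#' @return A list `features`, `labels` with synthetic rows appended (named
#'   `synth_*`); returned unchanged when already balanced.
#' @export
smote <- function(features, labels, k = 5, seed = 1) {
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) ln_stop("features/labels length mismatch")
  tab <- sort(table(labels))
  if (length(tab) != 2) ln_stop("need exactly two classes")
  minority <- names(tab)[1]
  n_min <- tab[[1]]; n_maj <- tab[[2]]
  if (n_min < 2) ln_stop("minority class has < 2 samples")
  if (n_min <= k) {
    ln_warn("minority count %d <= k = %d; k reduced to %d", n_min, k, n_min - 1)
    k <- n_min - 1
  }
  need <- n_maj - n_min
  if (need == 0) return(list(features = features, labels = labels))
  min_idx <- which(labels == minority)
  X <- features[min_idx, , drop = FALSE]
  dmat <- as.matrix(stats::dist(X))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)
  synth <- with_seed(seed, {
    t(vapply(seq_len(need), function(i) {
      base <- sample.int(nrow(X), 1)
      nb <- nn[base, sample.int(k, 1)]
      u <- stats::runif(1)
      X[base, ] + u * (X[nb, ] - X[base, ])
    }, numeric(ncol(X))))
  })
  rownames(synth) <- sprintf("synth_%03d", seq_len(need))
  list(features = rbind(features, synth),
       labels = c(labels, rep(minority, need)))
}

#' Cross-validated LASSO logistic regression
#'
#' L1-penalized logistic regression over a decreasing lambda path with
#' stratified k-fold cross-validation minimizing mean binomial deviance
#' (via [glmnet::cv.glmnet()]; features are standardized internally and
#' coefficients reported on the original scale). The selected genes are
#' those with non-zero coefficients at `lambda_min` (a `lambda_1se` rule is
#' available via `rule`).
#'
#' @param features Numeric matrix, samples x genes.
#' @param labels Two-class vector aligned with rows.
#' @param folds Number of CV folds (>= 2; each class needs >= `folds`... at
#'   least one member per fold).
#' @param seed Integer seed (fold assignment).
#' @param positive Positive-class label (probabilities refer to it).
#' @param rule `"min"` (default) or `"1se"`.
#' @return A `lasso_fit` list: `fit` (the cv.glmnet object), `lambda_path`,
#'   `cv` (tibble `lambda`, `deviance`, `se`, `nonzero`), `lambda_min`,
#'   `lambda_choice`, `selected` (tibble `gene`, `coefficient`),
#'   `intercept`, `positive_class`, `levels`.
#' @export
lasso_cv <- function(features, labels, folds = 10, seed = 1,
                     positive = "responder", rule = c("min", "1se")) {
  rule <- match.arg(rule)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) ln_stop("need exactly two classes")
  if (!positive %in% classes) ln_stop("positive class '%s' absent", positive)
  negative <- setdiff(classes, positive)
  y <- factor(labels, levels = c(negative, positive))
  counts <- table(y)
  folds <- min(folds, min(counts))
  if (folds < 2) ln_stop("too few samples per class for cross-validation")
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  cvfit <- glmnet::cv.glmnet(features, y, family = "binomial", foldid = foldid,
                             type.measure = "deviance", standardize = TRUE)
  lambda <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- stats::coef(cvfit, s = lambda)
  coefs <- as.numeric(beta)
  names(coefs) <- rownames(beta)
  nz <- coefs[-1][coefs[-1] != 0]
  structure(list(
    fit = cvfit,
    lambda_path = cvfit$lambda,
    cv = tibble(lambda = cvfit$lambda, deviance = cvfit$cvm, se = cvfit$cvsd,
                nonzero = cvfit$nzero),
    lambda_min = cvfit$lambda.min,
    lambda_choice = lambda,
    selected = tibble(gene = names(nz), coefficient = unname(nz)),
    intercept = unname(coefs[1]),
    positive_class = positive,
    levels = c(negative, positive)
  ), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda = %.4g; %d gene(s) selected; positive class '%s'\n",
              x$lambda_choice, nrow(x$selected), x$positive_class))
  invisible(x)
}

#' Predict positive-class probabilities from a LASSO fit
#'
#' @param object A `lasso_fit`.
#' @param newdata Numeric matrix, samples x genes (same columns as training).
#' @param ... Unused.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  drop(stats::predict(object$fit, newx = newdata, s = object$lambda_choice,
                      type = "response"))
}

#' @rdname tidy.expr_matrix
#' @export
tidy.lasso_fit <- function(x, ...) x$selected

#' Glance methods for fitted objects
#'
#' One-row summaries in the broom style.
#'
#' @param x A fitted object (`perm_report`, `ddc_model`, `lasso_fit`).
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.perm_report <- function(x, ...) {
  tibble(observed_mean_diff = x$observed_mean_diff, observed_p = x$observed_p,
         empirical_p = x$empirical_p, n_perm = x$n_perm)
}

#' @rdname glance.perm_report
#' @export
glance.lasso_fit <- function(x, ...) {
  at <- which.min(abs(x$cv$lambda - x$lambda_choice))
  tibble(lambda = x$lambda_choice, lambda_min = x$lambda_min,
         n_selected = nrow(x$selected), cv_deviance = x$cv$deviance[at],
         intercept = x$intercept)
}

#' Re-rank LASSO-selected genes by hub centrality
#'
#' Restricts the network to the subgraph induced by the selected genes,
#' computes the five hub centralities with [top_k_aggregate()], and flags as
#' top regulatory the genes that are both high-rank (in at least
#' `flag_min_methods` of the five top-k lists) and response DEGs.
#'
#' @param g Interaction network (igraph, named vertices).
#' @param selected Character vector of LASSO-selected genes.
#' @param k Top-k per method.
#' @param seed Seed for the EPC percolation.
#' @param response_degs Character vector of response-DEG symbols.
#' @param epc_iters,epsilon Centrality parameters.
#' @param min_degree Degree exclusion threshold within the subnetwork
#'   (default 0: no exclusion in these small subgraphs).
#' @param flag_min_methods Minimum top-k memberships for the flag.
#' @return A `hub_score_table` tibble with extra columns `is_response_deg`
#'   and `top_regulatory`; a warning when nothing is flagged.
#' @export
rank_selected_genes <- function(g, selected, k = 10, seed = 1,
                                response_degs = character(), epc_iters = 100,
                                epsilon = 1.7, min_degree = 0,
                                flag_min_methods = 4) {
  present <- intersect(selected, igraph::V(g)$name)
  if (!length(present)) ln_stop("no selected gene is present in the network")
  sub <- igraph::induced_subgraph(g, present)
  scores <- all_centralities(sub, epc_iters = epc_iters, epsilon = epsilon,
                             seed = seed)
  tab <- top_k_aggregate(scores, k = k, min_degree = min_degree)
  tab$is_response_deg <- tab$gene %in% response_degs
  tab$top_regulatory <- tab$is_response_deg & tab$selected_count >= flag_min_methods
  if (!any(tab$top_regulatory))
    ln_warn("no selected gene is both high-rank and a response DEG")
  tab
}

#' ROC area under the curve (Mann-Whitney estimator)
#'
#' Ties count one half. Both classes must be present.
#'
#' @param scores Numeric prediction scores.
#' @param labels Two-class vector aligned with `scores`.
#' @param positive Positive-class label.
#' @return The AUC.
#' @export
roc_auc <- function(scores, labels, positive = "responder") {
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) ln_stop("both classes must be present")
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Structural-components variance estimate with a Wald interval clipped to
#' `[0, 1]`. Zero variance (e.g. perfect separation) yields the degenerate
#' interval `(AUC, AUC)` with a warning.
#'
#' @param scores Numeric prediction scores.
#' @param labels Two-class vector (>= 2 per class).
#' @param level Confidence level.
#' @param positive Positive-class label.
#' @return A list `auc`, `low`, `high`, `level`.
#' @export
auc_ci_delong <- function(scores, labels, level = 0.95, positive = "responder") {
  labels <- as.character(labels)
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  if (length(x) < 2 || length(y) < 2) ln_stop("need >= 2 samples per class")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var_auc <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
  if (!is.finite(var_auc) || var_auc <= 0) {
    ln_warn("zero DeLong variance; degenerate interval (%.3f, %.3f)", auc, auc)
    return(list(auc = auc, low = auc, high = auc, level = level))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       low = max(0, auc - z * sqrt(var_auc)),
       high = min(1, auc + z * sqrt(var_auc)),
       level = level)
}

#' Confusion-matrix classification metrics
#'
#' Standard accuracy, precision (`TP/(TP+FP)`), recall (`TP/(TP+FN)`) and
#' F1 (`2PR/(P+R)`), with the responder class positive by default. With no
#' predicted positives, precision (and F1) are `NA` with a warning.
#'
#' @param predicted Predicted class labels (or probabilities of the positive
#'   class, thresholded at 0.5).
#' @param labels True class labels.
#' @param positive Positive-class label.
#' @param negative Negative-class label (inferred from `labels` if omitted).
#' @return A one-row tibble `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
classification_metrics <- function(predicted, labels, positive = "responder",
                                   negative = NULL) {
  labels <- as.character(labels)
  negative <- negative %||% setdiff(unique(labels), positive)[1]
  if (is.numeric(predicted))
    predicted <- ifelse(predicted >= 0.5, positive, negative)
  if (length(predicted) != length(labels)) ln_stop("length mismatch")
  tp <- sum(predicted == positive & labels == positive)
  fp <- sum(predicted == positive & labels != positive)
  tn <- sum(predicted != positive & labels != positive)
  fn <- sum(predicted != positive & labels == positive)
  if (tp + fp == 0) ln_warn("no predicted positives; precision undefined")
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(labels),
         precision = precision, recall = recall, f1 = f1)
}

#' Per-cluster SMOTE + LASSO response models
#'
#' For each disease-defining cluster: restricts the feature space to the
#' cluster's genes, splits the cohort into stratified train/test sets,
#' balances the training set with SMOTE, fits a cross-validated LASSO,
#' and evaluates AUC (with DeLong CI) on the training, testing and entire
#' sets — all on original (non-synthetic) samples — plus confusion-matrix
#' metrics on the external validation cohort. Test and validation samples
#' never enter SMOTE or cross-validation.
#'
#' @param cohort Response [expression_matrix()] (labels
#'   `responder`/`non-responder`).
#' @param validation Optional external validation [expression_matrix()]
#'   sharing the panel genes (`NULL` skips confusion metrics).
#' @param ddc A `ddc_model` (or tibble `gene`, `cluster`) assigning panel
#'   genes to clusters.
#' @param config An [ln_config()] (uses `split_ratio`, `smote_k`, `cv_folds`,
#'   `seed`).
#' @param positive Positive-class label.
#' @return A tibble of class `response_models`, one row per modelled cluster,
#'   sorted by decreasing test AUC: cluster id, gene counts, selected genes
#'   (list column), train/test/all AUCs with CI bounds, and validation
#'   confusion metrics. Clusters with fewer than 2 genes are skipped with a
#'   warning. Attribute `fits` holds the per-cluster `lasso_fit` objects.
#' @export
run_per_cluster_models <- function(cohort, validation = NULL, ddc,
                                   config = ln_config(),
                                   positive = "responder") {
  assignment <- if (inherits(ddc, "ddc_model")) tidy(ddc) else ddc
  clusters <- sort(unique(assignment$cluster))
  fits <- list()
  rows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    genes <- intersect(assignment$gene[assignment$cluster == cl],
                       em_genes(cohort))
    if (!is.null(validation)) genes <- intersect(genes, em_genes(validation))
    if (length(genes) < 2) {
      ln_warn("cluster %s has %d usable gene(s); skipped", cl, length(genes))
      next
    }
    seed_cl <- spawn_seed(config$seed, ci)
    parts <- split_train_test(cohort, ratio = config$split_ratio, seed = seed_cl)
    x_train <- t(parts$train$values[genes, , drop = FALSE])
    x_test <- t(parts$test$values[genes, , drop = FALSE])
    x_all <- t(cohort$values[genes, , drop = FALSE])
    bal <- smote(x_train, parts$train$labels, k = config$smote_k, seed = seed_cl)
    fit <- lasso_cv(bal$features, bal$labels, folds = config$cv_folds,
                    seed = seed_cl, positive = positive)
    ev <- function(x, labs) {
      p <- predict(fit, x)
      ci_ <- suppressWarnings(auc_ci_delong(p, labs, positive = positive))
      list(auc = ci_$auc, low = ci_$low, high = ci_$high)
    }
    tr <- ev(x_train, parts$train$labels)
    te <- ev(x_test, parts$test$labels)
    al <- ev(x_all, cohort$labels)
    val <- if (!is.null(validation)) {
      xv <- t(validation$values[genes, , drop = FALSE])
      suppressWarnings(
        classification_metrics(predict(fit, xv), validation$labels,
                               positive = positive))
    } else tibble(tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
                  fn = NA_integer_, accuracy = NA_real_, precision = NA_real_,
                  recall = NA_real_, f1 = NA_real_)
    fits[[cl]] <- fit
    rows[[cl]] <- dplyr::bind_cols(
      tibble(cluster = cl, n_genes = length(genes),
             n_selected = nrow(fit$selected),
             selected_genes = list(fit$selected$gene),
             auc_train = tr$auc, auc_train_low = tr$low, auc_train_high = tr$high,
             auc_test = te$auc, auc_test_low = te$low, auc_test_high = te$high,
             auc_all = al$auc, auc_all_low = al$low, auc_all_high = al$high,
             split_seed = seed_cl),
      val)
  }
  if (!length(rows)) ln_stop("no cluster had enough genes to model")
  res <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$auc_test))
  attr(res, "fits") <- fits
  class(res) <- c("response_models", class(res))
  res
}
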