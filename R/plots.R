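#' Plot the permutation null of the signature
#'
#' Scatter of background mean ssGSEA difference against -log10 Wilcoxon p,
#' with the observed signature highlighted.
#'
#' @param object A `perm_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_report <- function(object, ...) {
  bg <- object$background
  ggplot2::ggplot(bg, ggplot2::aes(x = abs(.data$mean_diff), y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2,
                        colour = "darkgreen") +
    ggplot2::annotate("point", x = abs(object$observed_mean_diff),
                      y = -log10(max(object$observed_p, 1e-300)),
                      colour = "red", size = 2.5) +
    ggplot2::labs(x = "|mean ssGSEA difference| (case - control)",
                  y = "-log10 Wilcoxon p",
                  title = sprintf("Permutation null (n = %d), empirical p = %.3g",
                                  object$n_perm, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Elbow plot of a clustering model
#'
#' @param object A `ddc_model` fitted with `k = "auto"` (needs its WSS
#'   curve), or pass a curve from [wss_curve()] to `plot_wss()`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddc_model <- function(object, ...) {
  if (is.null(object$wss_curve))
    ln_stop("model has no WSS curve; fit with k = \"auto\" or use plot_wss(wss_curve(...))")
  plot_wss(object$wss_curve, chosen_k = object$chosen_k)
}

#' @rdname autoplot.ddc_model
#' @param curve A tibble `k`, `wss`.
#' @param chosen_k Optional k to mark.
#' @export
plot_wss <- function(curve, chosen_k = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "k", y = "total within-cluster sum of squares") +
    ggplot2::theme_minimal()
  if (!is.null(chosen_k))
    p <- p + ggplot2::geom_vline(xintercept = chosen_k, linetype = 2,
                                 colour = "red")
  p
}

#' Heatmap of the panel-gene correlation profile
#'
#' Tile heatmap of Spearman's rho between DDG activity and each panel gene,
#' one column per dataset, rows ordered by cluster when a model is given.
#'
#' @param object A `ddc_profile`.
#' @param ddc Optional `ddc_model` used to order the rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddc_profile <- function(object, ddc = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"gene",
                              names_to = "dataset", values_to = "rho")
  lev <- if (!is.null(ddc)) names(sort(ddc$assignment)) else object$gene
  long$gene <- factor(long$gene, levels = lev)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$gene,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "panel gene", fill = "rho")
}

#' Per-cluster model performance plot
#'
#' Test-set AUC with DeLong confidence bounds, one row per cluster.
#'
#' @param object A `response_models` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_models <- function(object, ...) {
  df <- as_tibble(object)
  df$cluster <- factor(df$cluster, levels = rev(df$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc_test, y = .data$cluster)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$auc_test_low,
                                          xmax = .data$auc_test_high)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "test AUC (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' MA plot of a differential-expression table
#'
#' Mean expression against log2 fold change, highlighting genes passing the
#' |logFC| threshold convention used for response DEGs.
#'
#' @param degs Tibble from [moderated_t_test()].
#' @param logfc_threshold Highlight threshold.
#' @param alpha_bh Significance level on `q`.
#' @return A ggplot object.
#' @export
plot_ma <- function(degs, logfc_threshold = 1, alpha_bh = 0.05) {
  degs$status <- dplyr::case_when(
    degs$q < alpha_bh & abs(degs$logfc) >= logfc_threshold ~ "DEG |logFC| >= 1",
    degs$q < alpha_bh ~ "DEG |logFC| < 1",
    TRUE ~ "not significant")
  ggplot2::ggplot(degs, ggplot2::aes(x = .data$ave_expr, y = .data$logfc,
                                     colour = .data$status)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c("DEG |logFC| >= 1" = "red",
                                            "DEG |logFC| < 1" = "aquamarine3",
                                            "not significant" = "grey70")) +
    ggplot2::labs(x = "mean expression (A)", y = "log2 fold change (M)") +
    ggplot2::theme_minimal()
}
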