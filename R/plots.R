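#' Smile plot of per-feature fold change versus significance
#'
#' Scatter of `-log10(adjusted p)` against `log2(fold change)`; red points
#' mark features reduced in the HTN class, blue points features increased,
#' with the flagged (two-fold and FDR-significant) features emphasized.
#' Features with undefined fold change are omitted.
#'
#' @param x A [smile_table()].
#' @return A ggplot object.
#' @export
plot_smile <- function(x) {
  fdr <- attr(x, "fdr_level") %||% 0.05
  fc <- attr(x, "fc_cutoff") %||% 2
  d <- dplyr::filter(as_tibble(x), .data$fc_defined, !is.na(.data$p_adj))
  d$direction <- ifelse(d$log2_fc < 0, "reduced in HTN", "increased in HTN")
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, .data$neg_log10_p)) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed",
      colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-log2(fc), log2(fc)),
      linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction,
      alpha = .data$flagged)) +
    ggplot2::scale_colour_manual(values = c(
      "reduced in HTN" = "#c0392b", "increased in HTN" = "#2c6fbb")) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
      guide = "none") +
    ggplot2::labs(x = "log2 fold change (HTN / NC)",
      y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot smile_table
#' @export
autoplot.smile_table <- function(object, ...) plot_smile(object)

#' ROC curve of the EML score
#'
#' Empirical ROC of the ensemble score on the evaluation samples, annotated
#' with the AUC and its DeLong standard error.
#'
#' @param x An [eml_report()].
#' @return A ggplot object.
#' @export
plot_roc <- function(x) {
  sc <- x$scores
  thr <- c(Inf, sort(unique(sc$score), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    tibble(
      fpr = mean(sc$score[sc$group == "NC"] >= t),
      tpr = mean(sc$score[sc$group == "HTN"] >= t)
    )
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.65, y = 0.1,
      label = sprintf("AUC = %.3f ± %.3f", x$auc, x$auc_se)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' @method autoplot eml_report
#' @export
autoplot.eml_report <- function(object, ...) plot_roc(object)

#' EML score distribution by group
#'
#' @param x An [eml_report()].
#' @return A ggplot object (box plot with the Youden cutoff marked).
#' @export
plot_score_groups <- function(x) {
  ggplot2::ggplot(x$scores, ggplot2::aes(.data$group, .data$score,
    fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = 21) +
    ggplot2::geom_hline(yintercept = x$cutoff, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "EML score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' EML score versus septum width
#'
#' Scatter of the ensemble score against LV septum width (test samples)
#' with the least-squares line and the Pearson R^2.
#'
#' @param x An [eml_report()].
#' @param clinical Clinical tibble with `subject_id` and `septum_width`.
#' @return A ggplot object.
#' @export
plot_score_septum <- function(x, clinical) {
  d <- dplyr::inner_join(x$scores,
    dplyr::select(clinical, "subject_id", "septum_width"), by = "subject_id")
  lab <- if (!is.null(x$correlation)) {
    sprintf("R² = %.3f", x$correlation$r_squared)
  } else {
    NULL
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$septum_width, .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "black", linewidth = 0.5) +
    ggplot2::labs(x = "LV septum width (mm)", y = "EML score",
      colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(lab)) {
    p <- p + ggplot2::annotate("text", x = min(d$septum_width),
      y = max(d$score), label = lab, hjust = 0)
  }
  p
}

#' Hit counts of the relevance selection
#'
#' @param object A [run_boruta()] report.
#' @param top Number of features shown (default 30, by hit count).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boruta_report
#' @export
autoplot.boruta_report <- function(object, top = 30, ...) {
  d <- dplyr::slice_max(as_tibble(object), .data$hit_count, n = top,
    with_ties = FALSE)
  d$feature <- stats::reorder(d$feature, d$hit_count)
  ggplot2::ggplot(d, ggplot2::aes(.data$hit_count, .data$feature,
    fill = .data$decision)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "n_iterations") / 2,
      linetype = "dashed") +
    ggplot2::labs(x = "shadow-beating iterations", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
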