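#' Select models for the ensemble
#'
#' Retains the models whose accuracy strictly exceeds the gate (60% by
#' default). The gating and voting accuracy is the training-set
#' cross-validation accuracy, which also becomes the model's vote weight.
#'
#' @param zoo A `ctx_zoo` from [train_zoo()].
#' @param threshold Accuracy gate (default 0.6, strict `>`).
#' @param weight Which accuracy is used for the gate and the vote weight:
#'   `"cv_accuracy"` (default) or `"test_accuracy"`.
#' @return Tibble with columns `model` and `weight`.
#' @export
select_models <- function(zoo, threshold = 0.6,
                          weight = c("cv_accuracy", "test_accuracy")) {
  weight <- match.arg(weight)
  ok <- dplyr::filter(zoo, .data$status == "ok")
  if (nrow(ok) == 0) {
    abort("no successfully trained models available",
      class = "cardiotex_parameter_error")
  }
  acc <- if (weight == "cv_accuracy") {
    ok$cv_accuracy
  } else {
    vapply(ok$metrics, function(m) m$accuracy, numeric(1))
  }
  sel <- tibble(model = ok$model, weight = acc)[acc > threshold, ]
  if (nrow(sel) == 0) {
    abort(sprintf("no model exceeded the %.0f%% accuracy gate", 100 * threshold),
      class = "cardiotex_no_model_error")
  }
  sel
}

#' Ensemble machine-learning (EML) scores
#'
#' For every test sample, sums the signed weighted votes of the selected
#' models: each model contributes `+ accuracy x confidence` when it calls
#' the sample hypertensive (HTN) and `- accuracy x confidence` when it
#' calls it a control (NC).
#'
#' @param zoo A `ctx_zoo` from [train_zoo()].
#' @param selected Selection tibble from [select_models()].
#' @return Tibble `subject_id`, `group`, `score`.
#' @export
eml_scores <- function(zoo, selected) {
  ok <- dplyr::filter(zoo, .data$model %in% selected$model)
  contrib <- purrr::map2_dfr(ok$model, ok$predictions, function(m, pred) {
    if (is.null(pred)) {
      abort("selected model has no predictions", class = "cardiotex_parameter_error")
    }
    w <- selected$weight[selected$model == m]
    dplyr::mutate(pred,
      term = ifelse(.data$predicted == "HTN", 1, -1) * w * .data$confidence
    )
  })
  dplyr::summarise(
    dplyr::group_by(contrib, .data$subject_id, .data$group),
    score = sum(.data$term), .groups = "drop"
  )
}

#' Youden-optimal cutoff
#'
#' Scans candidate thresholds (midpoints between adjacent sorted unique
#' scores, plus one candidate below and above all scores) for the value
#' maximizing Youden's J = sensitivity + specificity - 1, with samples
#' scoring above the cutoff classified HTN. Ties are broken toward the
#' larger cutoff (higher specificity).
#'
#' @param scores Numeric scores.
#' @param labels Class labels (`"HTN"` / `"NC"`).
#' @return The cutoff value.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort("both classes must be present", class = "cardiotex_parameter_error")
  }
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (head(u, -1) + u[-1]) / 2, u[length(u)] + 1)
  j <- vapply(cand, function(ct) {
    m <- confusion_at_cutoff(scores, labels, ct)
    m$sensitivity + m$specificity - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[max(best)]
}

#' ROC AUC with DeLong standard error
#'
#' The AUC is the Mann-Whitney two-sample statistic (ties count 1/2); its
#' standard error comes from the DeLong structural components (placement
#' values), and the p-value tests AUC = 0.5 with a two-sided normal
#' approximation on the DeLong variance.
#'
#' @inheritParams youden_cutoff
#' @return List with `auc`, `se`, `p_value`, `n_pos`, `n_neg`.
#' @export
roc_delong <- function(scores, labels) {
  labels <- as.character(labels)
  xs <- scores[labels == "HTN"]
  ys <- scores[labels == "NC"]
  m <- length(xs)
  n <- length(ys)
  if (m == 0 || n == 0) {
    abort("both classes must be present", class = "cardiotex_parameter_error")
  }
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s <- (if (m > 1) var(v10) / m else 0) + (if (n > 1) var(v01) / n else 0)
  se <- sqrt(s)
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  list(auc = auc, se = se, p_value = p, n_pos = m, n_neg = n)
}

#' Correlation between EML score and septum width
#'
#' Pearson correlation with `R^2 = r^2` and the usual t-based p-value on
#' `n - 2` degrees of freedom.
#'
#' @param scores,septum_widths Paired numeric vectors (`n >= 3`).
#' @return List with `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate_septum <- function(scores, septum_widths) {
  if (length(scores) < 3 || length(scores) != length(septum_widths)) {
    abort("need >= 3 paired values", class = "cardiotex_parameter_error")
  }
  if (sd(scores) == 0 || sd(septum_widths) == 0) {
    abort("zero variance in scores or septum widths",
      class = "cardiotex_parameter_error")
  }
  ct <- cor.test(scores, septum_widths, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(scores))
}

#' Build the full EML report
#'
#' Gates the zoo at the accuracy threshold, computes the signed
#' accuracy-x-confidence ensemble score for every test sample, the
#' Youden-optimal cutoff on the test scores, the ROC AUC with DeLong SE,
#' the confusion-matrix metrics at the cutoff, per-group score summaries,
#' and (when a clinical table is supplied) the Pearson correlation between
#' score and septum width on the test samples.
#'
#' @param zoo A `ctx_zoo` from [train_zoo()].
#' @param threshold Accuracy gate (default 0.6).
#' @param clinical Optional clinical tibble with `subject_id` and
#'   `septum_width` used for the correlation analysis.
#' @inheritParams select_models
#' @return An object of class `eml_report`.
#' @export
eml_report <- function(zoo, threshold = 0.6, clinical = NULL,
                       weight = "cv_accuracy") {
  selected <- select_models(zoo, threshold, weight)
  scores <- eml_scores(zoo, selected)
  cutoff <- youden_cutoff(scores$score, scores$group)
  roc <- roc_delong(scores$score, scores$group)
  metrics <- confusion_at_cutoff(scores$score, scores$group, cutoff)
  group_summary <- dplyr::summarise(
    dplyr::group_by(scores, .data$group),
    mean = mean(.data$score), sd = sd(.data$score), n = dplyr::n(),
    .groups = "drop"
  )
  correlation <- NULL
  if (!is.null(clinical)) {
    joined <- dplyr::inner_join(scores,
      dplyr::select(clinical, "subject_id", "septum_width"),
      by = "subject_id")
    correlation <- correlate_septum(joined$score, joined$septum_width)
  }
  structure(
    list(
      selected_models = selected, scores = scores, cutoff = cutoff,
      auc = roc$auc, auc_se = roc$se, auc_p_value = roc$p_value,
      metrics = metrics, group_summary = group_summary,
      correlation = correlation, threshold = threshold
    ),
    class = "eml_report"
  )
}

#' @export
print.eml_report <- function(x, ...) {
  cat("<eml_report>", nrow(x$selected_models), "models ensembled;",
    sprintf("AUC %.3f +/- %.3f, cutoff %.3f, accuracy %.3f\n",
      x$auc, x$auc_se, x$cutoff, x$metrics$accuracy))
  if (!is.null(x$correlation)) {
    cat(sprintf("  score vs septum width: r = %.3f (R^2 = %.3f, p = %.2g)\n",
      x$correlation$r, x$correlation$r_squared, x$correlation$p_value))
  }
  invisible(x)
}
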