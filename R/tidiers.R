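# broom-style tidiers for the fitted result objects.

#' Tidy the classifier zoo
#'
#' @param x A `ctx_zoo` from [train_zoo()].
#' @param ... Unused.
#' @return One row per successfully trained model with cross-validation
#'   accuracy and the test-set confusion metrics.
#' @method tidy ctx_zoo
#' @export
tidy.ctx_zoo <- function(x, ...) {
  ok <- dplyr::filter(as_tibble(x), .data$status == "ok")
  dplyr::bind_cols(
    dplyr::select(ok, "model", "cv_accuracy"),
    dplyr::bind_rows(ok$metrics)
  )
}

#' @rdname tidy.ctx_zoo
#' @method glance ctx_zoo
#' @export
glance.ctx_zoo <- function(x, ...) {
  ok <- dplyr::filter(as_tibble(x), .data$status == "ok")
  tibble(
    n_models = nrow(x), n_trained = nrow(ok),
    mean_cv_accuracy = mean(ok$cv_accuracy),
    best_model = ok$model[which.max(ok$cv_accuracy)]
  )
}

#' Tidy an EML report
#'
#' @param x An [eml_report()].
#' @param ... Unused.
#' @return `tidy()`: per-sample scores with the cutoff classification;
#'   `glance()`: a one-row summary (AUC, SE, cutoff, metrics, correlation).
#' @method tidy eml_report
#' @export
tidy.eml_report <- function(x, ...) {
  dplyr::mutate(x$scores,
    predicted = ifelse(.data$score > x$cutoff, "HTN", "NC"))
}

#' @rdname tidy.eml_report
#' @method glance eml_report
#' @export
glance.eml_report <- function(x, ...) {
  tibble(
    n_models = nrow(x$selected_models),
    auc = x$auc, auc_se = x$auc_se, auc_p_value = x$auc_p_value,
    cutoff = x$cutoff,
    accuracy = x$metrics$accuracy,
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    r = x$correlation$r %||% NA_real_,
    r_squared = x$correlation$r_squared %||% NA_real_
  )
}

#' Tidy a relevance-selection report
#'
#' @param x A [run_boruta()] report.
#' @param ... Unused.
#' @return `tidy()`: the per-feature table; `glance()`: a one-row summary.
#' @method tidy boruta_report
#' @export
tidy.boruta_report <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.boruta_report
#' @method glance boruta_report
#' @export
glance.boruta_report <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_confirmed = sum(x$decision == "confirmed"),
    n_iterations = attr(x, "n_iterations"),
    rule = attr(x, "rule")
  )
}
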