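#' Configure an end-to-end pipeline run
#'
#' Collects every stage's parameters into a single validated object.
#' Defaults mirror the reference analysis (70:30 split, 60% accuracy gate,
#' 5% FDR with two-fold change, all eleven models) at desk-scale
#' computational settings.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param spec A [cohort_spec()] (defaults to the calibrated cohort at the
#'   published sample sizes).
#' @param split_ratio Training fraction.
#' @param models Models to train (see [model_zoo_names()]).
#' @param accuracy_gate Ensemble inclusion gate on cross-validation
#'   accuracy (strict `>`).
#' @param cv_folds,tuning_budget,num_trees Zoo settings.
#' @param boruta_iter,boruta_trees,boruta_rule Relevance-selection
#'   settings; Boruta runs on the training split.
#' @param fdr_level,fc_cutoff Smile-table thresholds.
#' @param min_cor,max_cor,max_identical Screening thresholds.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes all
#'   stage artifacts there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, spec = NULL, split_ratio = 0.7,
                            models = model_zoo_names(), accuracy_gate = 0.6,
                            cv_folds = 10, tuning_budget = 2, num_trees = 300,
                            boruta_iter = 200, boruta_trees = 100,
                            boruta_rule = "binomial", fdr_level = 0.05,
                            fc_cutoff = 2, min_cor = 1e-5, max_cor = 0.95,
                            max_identical = 0.9, out_dir = NULL) {
  spec <- spec %||% cohort_spec(seed = child_seed(seed, 1))
  stopifnot(split_ratio > 0, split_ratio < 1, accuracy_gate >= 0,
    accuracy_gate < 1, fdr_level > 0, fdr_level < 1, fc_cutoff > 1,
    boruta_iter >= 1, cv_folds >= 2)
  structure(
    list(
      seed = as.integer(seed), spec = spec, split_ratio = split_ratio,
      models = models, accuracy_gate = accuracy_gate, cv_folds = cv_folds,
      tuning_budget = tuning_budget, num_trees = num_trees,
      boruta_iter = boruta_iter, boruta_trees = boruta_trees,
      boruta_rule = boruta_rule, fdr_level = fdr_level,
      fc_cutoff = fc_cutoff, min_cor = min_cor, max_cor = max_cor,
      max_identical = max_identical, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full radiomics analysis pipeline
#'
#' Executes every stage in order: cohort simulation, feature extraction,
#' stratified split, training-set screening and autoscaling, classifier
#' zoo, EML ensemble report (with score-vs-septum correlation on the test
#' samples), Boruta-style relevance selection on the training split, and
#' the raw-scale smile table over all subjects. When `config$out_dir` is
#' set, each stage's artifact is written there (CSV/JSON) together with a
#' `summary.json` stamped with the seed and a configuration hash.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `cohort`,
#'   `features`, `screening`, `zoo`, `eml`, `boruta`, `smile`, `summary`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must be a pipeline_config", class = "cardiotex_parameter_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
        conditionMessage(e)), class = "cardiotex_stage_error")
    })
  }
  cohort <- stage("simulate", generate_cohort(config$spec))
  features <- stage("extract", extract_features(cohort))
  parts <- stage("split",
    split_cohort(features, config$split_ratio, child_seed(config$seed, 2)))
  screening <- stage("screen", screen_features(parts$train, config$min_cor,
    config$max_cor, config$max_identical))
  scaled <- stage("autoscale", autoscale(
    apply_screen(parts$train, screening),
    apply_screen(parts$test, screening)
  ))
  zoo <- stage("train", train_zoo(scaled$train, scaled$test,
    models = config$models, cv_folds = config$cv_folds,
    tuning_budget = config$tuning_budget, num_trees = config$num_trees,
    seed = child_seed(config$seed, 3)))
  clinical <- dplyr::select(cohort, -"image", -"roi")
  eml <- stage("eml", eml_report(zoo, config$accuracy_gate, clinical))
  boruta <- stage("boruta", run_boruta(
    apply_screen(parts$train, screening),
    n_iter = config$boruta_iter, seed = child_seed(config$seed, 4),
    num_trees = config$boruta_trees, rule = config$boruta_rule
  ))
  smile <- stage("stats", smile_table(
    dplyr::select(features, -"subject_id"),
    config$fdr_level, config$fc_cutoff
  ))

  model_acc <- dplyr::transmute(
    dplyr::filter(zoo, .data$status == "ok"),
    model = .data$model, cv_accuracy = .data$cv_accuracy,
    test_accuracy = vapply(.data$metrics, function(m) m$accuracy, numeric(1))
  )
  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_subjects = nrow(cohort),
    n_features = length(feature_columns(features)),
    n_retained = length(screening$retained),
    models = model_acc,
    ensemble = list(
      n_selected = nrow(eml$selected_models),
      selected = eml$selected_models$model,
      accuracy = eml$metrics$accuracy,
      sensitivity = eml$metrics$sensitivity,
      specificity = eml$metrics$specificity,
      auc = eml$auc, auc_se = eml$auc_se, cutoff = eml$cutoff,
      score_group_means = eml$group_summary,
      correlation_r = eml$correlation$r,
      correlation_r_squared = eml$correlation$r_squared
    ),
    n_smile_flagged = sum(smile$flagged, na.rm = TRUE),
    n_boruta_confirmed = sum(boruta$decision == "confirmed")
  )

  result <- structure(
    list(cohort = cohort, features = features, screening = screening,
      zoo = zoo, eml = eml, boruta = boruta, smile = smile,
      summary = summary),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline(result, config)
  result
}

write_pipeline <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dplyr::select(result$features, -dplyr::any_of(character())),
    file.path(dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(result$screening),
    file.path(dir, "screening.json"), digits = NA)
  zoo_out <- dplyr::select(result$zoo, -"params")
  jsonlite::write_json(zoo_out, file.path(dir, "model_results.json"),
    digits = NA, na = "null")
  jsonlite::write_json(
    result$eml[c("selected_models", "cutoff", "auc", "auc_se",
      "auc_p_value", "metrics", "group_summary", "correlation")],
    file.path(dir, "eml_report.json"), digits = NA, na = "null"
  )
  write.csv(result$eml$scores, file.path(dir, "eml_scores.csv"),
    row.names = FALSE)
  write.csv(result$boruta, file.path(dir, "boruta_report.csv"),
    row.names = FALSE)
  write.csv(result$smile, file.path(dir, "group_comparison.csv"),
    row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
    digits = NA, auto_unbox = TRUE, na = "null")
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>", s$n_subjects, "subjects,", s$n_features,
    "features (", s$n_retained, "retained )\n")
  cat("  ensemble:", s$ensemble$n_selected, "models, accuracy",
    round(s$ensemble$accuracy, 3), ", AUC", round(s$ensemble$auc, 3), "\n")
  cat("  smile-flagged:", s$n_smile_flagged,
    "; boruta-confirmed:", s$n_boruta_confirmed, "\n")
  invisible(x)
}
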