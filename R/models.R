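#' Stratified train/test split
#'
#' Splits the feature table by subject into training and test parts at the
#' requested ratio (70:30 by default), stratified by class with
#' nearest-integer (half-up) rounding of the per-class training counts, so
#' class proportions in each part stay within a few percentage points of
#' the whole table.
#'
#' @param table Feature tibble with `subject_id` and `group` columns.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed controlling the assignment.
#' @return List with tibbles `train` and `test`.
#' @examples
#' # 158 subjects at 0.7 -> 111 train (58 HTN + 53 NC) / 47 test
#' @export
split_cohort <- function(table, ratio = 0.7, seed = 1) {
  counts <- table(table$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("both classes must be present with >= 2 members each",
      class = "cardiotex_parameter_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx_train <- unlist(lapply(unique(table$group), function(g) {
    ix <- which(table$group == g)
    n_tr <- floor(ratio * length(ix) + 0.5)
    sample(ix, n_tr)
  }))
  list(
    train = table[sort(idx_train), , drop = FALSE],
    test = table[setdiff(seq_len(nrow(table)), idx_train), , drop = FALSE]
  )
}

#' Screen features on the training table
#'
#' Applies the three screening criteria, on training data only: a feature
#' is removed when (a) its Pearson correlation with the binary class label
#' is below `min_cor` (uninformative) or above `max_cor` (label-mirroring),
#' (b) more than `max_identical` of its values are identical (unstable), or
#' (c) it has any missing value. Criteria are checked in the order missing,
#' stability, correlation; each feature is reported under the first
#' criterion it fails.
#'
#' @param train Training feature tibble (`subject_id`, `group`, features).
#' @param min_cor,max_cor Correlation-screen bounds (defaults 1e-5, 0.95).
#' @param max_identical Maximum tolerated fraction of identical values
#'   (default 0.9).
#' @return An object of class `screening_report`: list of feature-name
#'   vectors `removed_by_missing`, `removed_by_stability`,
#'   `removed_by_correlation`, `retained`.
#' @export
screen_features <- function(train, min_cor = 1e-5, max_cor = 0.95,
                            max_identical = 0.9) {
  feats <- feature_columns(train)
  y <- as.numeric(group_factor(train$group)) - 1
  n <- nrow(train)
  missing <- character()
  unstable <- character()
  correlated <- character()
  for (f in feats) {
    v <- train[[f]]
    if (anyNA(v)) {
      missing <- c(missing, f)
    } else if (max(table(v)) > max_identical * n) {
      unstable <- c(unstable, f)
    } else {
      r <- suppressWarnings(stats::cor(v, y))
      if (is.na(r) || abs(r) < min_cor || abs(r) > max_cor) {
        correlated <- c(correlated, f)
      }
    }
  }
  structure(
    list(
      removed_by_missing = missing,
      removed_by_stability = unstable,
      removed_by_correlation = correlated,
      retained = setdiff(feats, c(missing, unstable, correlated))
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>", length(x$retained), "retained;",
    length(x$removed_by_missing), "missing,",
    length(x$removed_by_stability), "unstable,",
    length(x$removed_by_correlation), "correlation-screened\n")
  invisible(x)
}

#' Apply a screening report to a feature table
#'
#' @param table Feature tibble.
#' @param report A `screening_report`.
#' @return The tibble restricted to `subject_id`, `group` and retained
#'   features.
#' @export
apply_screen <- function(table, report) {
  dplyr::select(table, "subject_id", "group",
    dplyr::all_of(report$retained))
}

#' Autoscale train and test feature tables
#'
#' Mean-centers and scales every feature to unit sample SD using parameters
#' estimated on the training table only; the test table is transformed with
#' the training means and SDs (no test-set leakage). A feature value missing
#' in the test table (screening sees only the training part) is imputed with
#' the training mean, i.e. 0 on the scaled scale.
#'
#' @param train,test Feature tibbles sharing the same feature columns.
#' @return List with `train`, `test`, and `scaling` (a tibble of the means
#'   and SDs used).
#' @export
autoscale <- function(train, test = NULL) {
  feats <- feature_columns(train)
  mu <- vapply(train[feats], mean, numeric(1))
  sigma <- vapply(train[feats], sd, numeric(1))
  if (any(sigma == 0 | is.na(sigma))) {
    abort("zero-SD feature present; screen before autoscaling",
      class = "cardiotex_parameter_error")
  }
  rescale <- function(tbl, impute = FALSE) {
    for (f in feats) {
      v <- (tbl[[f]] - mu[[f]]) / sigma[[f]]
      if (impute) v[is.na(v)] <- 0
      tbl[[f]] <- v
    }
    tbl
  }
  list(
    train = rescale(train),
    test = if (!is.null(test)) rescale(test, impute = TRUE) else NULL,
    scaling = tibble(feature = feats, mean = unname(mu), sd = unname(sigma))
  )
}

model_zoo_names <- function() {
  c("PLS-DA", "NB", "GLM", "LR", "FLM", "DL", "DT", "RF", "GBT", "aNN", "SVM")
}

# --- model backends ----------------------------------------------------
# Each fitter returns a function(newx) -> numeric vector of P(HTN).
# `x` is the numeric feature matrix, `y` the NC/HTN factor.

fit_backend <- function(model, x, y, params, num_trees) {
  switch(model,
    "PLS-DA" = {
      fit <- mixOmics::plsda(x, y, ncomp = params$ncomp)
      function(newx) {
        pr <- predict(fit, newx)$predict[, , params$ncomp, drop = FALSE]
        pmin(pmax(pr[, "HTN", 1], 0), 1)
      }
    },
    "NB" = {
      fit <- e1071::naiveBayes(x, y, laplace = params$laplace)
      function(newx) predict(fit, newx, type = "raw")[, "HTN"]
    },
    "GLM" = ,
    "LR" = {
      alpha <- if (model == "GLM") 0.5 else 0
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
        lambda = params$lambda)
      function(newx) {
        as.numeric(predict(fit, newx, s = params$lambda, type = "response"))
      }
    },
    "FLM" = {
      fit <- e1071::svm(x, y, kernel = "linear", cost = params$cost,
        probability = TRUE, scale = FALSE)
      function(newx) {
        attr(predict(fit, newx, probability = TRUE), "probabilities")[, "HTN"]
      }
    },
    "DL" = ,
    "aNN" = {
      fit <- nnet::nnet(x, class.ind(y), size = params$size,
        decay = params$decay, maxit = 120, softmax = TRUE, trace = FALSE,
        MaxNWts = 100000)
      function(newx) predict(fit, newx)[, "HTN"]
    },
    "DT" = {
      df <- data.frame(y = y, x, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = df, method = "class",
        control = rpart::rpart.control(cp = params$cp))
      function(newx) {
        predict(fit, data.frame(newx, check.names = FALSE))[, "HTN"]
      }
    },
    "RF" = {
      fit <- ranger::ranger(
        x = x, y = y, num.trees = num_trees, probability = TRUE,
        num.threads = 1, seed = params$fit_seed %||% 1
      )
      function(newx) predict(fit, newx, num.threads = 1)$predictions[, "HTN"]
    },
    "GBT" = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "HTN"))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
          max_depth = params$max_depth, eta = params$eta, nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0
      )
      function(newx) predict(fit, xgboost::xgb.DMatrix(newx))
    },
    "SVM" = {
      fit <- e1071::svm(x, y, kernel = "radial", cost = params$cost,
        probability = TRUE, scale = FALSE)
      function(newx) {
        attr(predict(fit, newx, probability = TRUE), "probabilities")[, "HTN"]
      }
    },
    abort(paste("unknown model:", model), class = "cardiotex_parameter_error")
  )
}

class.ind <- function(y) {
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

# Hyperparameter grids, ordered by preference; `tuning_budget` takes the
# first k configurations.
model_grid <- function(model) {
  switch(model,
    "PLS-DA" = list(list(ncomp = 2), list(ncomp = 1), list(ncomp = 3)),
    "NB" = list(list(laplace = 0), list(laplace = 1)),
    "GLM" = list(list(lambda = 0.05), list(lambda = 0.2), list(lambda = 0.01)),
    "LR" = list(list(lambda = 0.05), list(lambda = 0.2), list(lambda = 0.01)),
    "FLM" = list(list(cost = 0.1), list(cost = 1), list(cost = 0.01)),
    "DL" = list(list(size = 5, decay = 1), list(size = 5, decay = 0.3)),
    "DT" = list(list(cp = 0.01), list(cp = 0.05), list(cp = 0.1)),
    "RF" = list(list()),
    "GBT" = list(
      list(nrounds = 60, max_depth = 3, eta = 0.3),
      list(nrounds = 60, max_depth = 2, eta = 0.3),
      list(nrounds = 100, max_depth = 4, eta = 0.1)
    ),
    "aNN" = list(list(size = 3, decay = 0.1), list(size = 5, decay = 0.5)),
    "SVM" = list(list(cost = 1), list(cost = 10), list(cost = 0.1))
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (g in levels(y)) {
    ix <- which(y == g)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

cv_accuracy_for <- function(model, x, y, params, folds, num_trees, seed) {
  k <- max(folds)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    set.seed(child_seed(seed, f))
    predictor <- fit_backend(model, x[tr, , drop = FALSE], y[tr],
      params, num_trees)
    p <- predictor(x[!tr, , drop = FALSE])
    correct <- correct + sum((p > 0.5) == (y[!tr] == "HTN"))
  }
  correct / length(y)
}

#' Train and evaluate the classifier zoo
#'
#' Trains the requested classification models on the (screened, autoscaled)
#' training table, with per-model hyperparameter selection by stratified
#' k-fold cross-validation accuracy on the training set only, then
#' evaluates each fitted model on the test table. The per-sample confidence
#' is the model's predicted-class membership probability (in `[0, 1]`).
#' A model that errors during fitting is recorded with status `"failed"`
#' and excluded from downstream ensembling.
#'
#' @param train,test Autoscaled feature tibbles.
#' @param models Character vector of model names (default all eleven:
#'   `r paste(model_zoo_names(), collapse = ", ")`).
#' @param cv_folds Folds for cross-validation (default 10).
#' @param tuning_budget Number of hyperparameter configurations tried per
#'   model (default 2; 1 = fixed defaults).
#' @param num_trees Trees for the random-forest model (default 300).
#' @param seed Integer seed; results are deterministic given it.
#' @return An object of class `ctx_zoo`: tibble with one row per model
#'   (`model`, `status`, `cv_accuracy`, `params`, nested `predictions` and
#'   `metrics`).
#' @export
train_zoo <- function(train, test, models = model_zoo_names(), cv_folds = 10,
                      tuning_budget = 2, num_trees = 300, seed = 1) {
  feats <- feature_columns(train)
  x <- as.matrix(train[feats])
  y <- group_factor(train$group)
  x_test <- as.matrix(test[feats])
  y_test <- group_factor(test$group)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  rows <- purrr::imap(setNames(models, models), function(model, nm) {
    idx <- match(model, model_zoo_names())
    mseed <- child_seed(seed, if (is.na(idx)) 99 else idx)
    set.seed(mseed)
    folds <- stratified_folds(y, cv_folds)
    grid <- head(model_grid(model), max(1, tuning_budget))
    out <- tryCatch({
      cvs <- vapply(seq_along(grid), function(gi) {
        cv_accuracy_for(model, x, y, grid[[gi]], folds, num_trees,
          child_seed(mseed, 100 + gi))
      }, numeric(1))
      best <- which.max(cvs)
      params <- grid[[best]]
      params$fit_seed <- child_seed(mseed, 999)
      set.seed(params$fit_seed)
      predictor <- fit_backend(model, x, y, params, num_trees)
      p_htn <- as.numeric(predictor(x_test))
      pred <- ifelse(p_htn > 0.5, "HTN", "NC")
      conf <- pmin(pmax(ifelse(p_htn > 0.5, p_htn, 1 - p_htn), 0), 1)
      metrics <- confusion_metrics(
        tp = sum(pred == "HTN" & y_test == "HTN"),
        fp = sum(pred == "HTN" & y_test == "NC"),
        tn = sum(pred == "NC" & y_test == "NC"),
        fn = sum(pred == "NC" & y_test == "HTN")
      )
      tibble(
        model = model, status = "ok", cv_accuracy = cvs[best],
        params = list(grid[[best]]),
        predictions = list(tibble(
          subject_id = test$subject_id, group = as.character(y_test),
          predicted = pred, confidence = conf, p_htn = p_htn
        )),
        metrics = list(metrics)
      )
    }, error = function(e) {
      tibble(
        model = model, status = paste("failed:", conditionMessage(e)),
        cv_accuracy = NA_real_, params = list(NULL),
        predictions = list(NULL), metrics = list(NULL)
      )
    })
    out
  })
  structure(dplyr::bind_rows(rows), class = c("ctx_zoo", class(tibble())))
}
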