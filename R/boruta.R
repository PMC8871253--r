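#' Shadow copy of a feature table
#'
#' Returns a table of the same width whose every column is an independent
#' random permutation of the original column (marginal distributions
#' preserved exactly, associations with the label destroyed). Shadow
#' columns are prefixed `shadow_`.
#'
#' @param x Feature tibble or data frame (features only, >= 2 rows).
#' @return Tibble of shadow features.
#' @export
make_shadow <- function(x) {
  if (nrow(x) < 2) abort("need >= 2 rows", class = "cardiotex_parameter_error")
  sh <- dplyr::mutate(as_tibble(x),
    dplyr::across(dplyr::everything(), ~ .x[sample.int(length(.x))]))
  names(sh) <- paste0("shadow_", names(sh))
  sh
}

#' One shadow-feature relevance iteration
#'
#' Attaches a fresh shadow copy to the feature table (doubling the column
#' count), trains a random forest on the combined table, measures
#' impurity-decrease importance for every column, and flags a real feature
#' as a "hit" when its importance strictly exceeds the maximum importance
#' among the shadow features. Shadow columns are never hit candidates.
#'
#' @param x Feature tibble (features only).
#' @param y Binary class labels (factor or character `"HTN"`/`"NC"`).
#' @param num_trees Trees per forest (default 100).
#' @param seed Seed for the shadow permutation and the forest.
#' @return Named logical vector of hits, one per feature of `x`.
#' @export
boruta_iteration <- function(x, y, num_trees = 100, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  combined <- dplyr::bind_cols(as_tibble(x), make_shadow(x))
  fit <- ranger::ranger(
    x = as.data.frame(combined), y = group_factor(y),
    num.trees = num_trees, importance = "impurity",
    num.threads = 1, seed = seed
  )
  imp <- fit$variable.importance
  shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
  hits <- imp[names(x)] > shadow_max
  setNames(as.logical(hits), names(x))
}

#' Shadow-feature (Boruta-style) relevance selection
#'
#' Repeats [boruta_iteration()] `n_iter` times with fresh shadow
#' permutations, accumulating per-feature hit counts. A feature is
#' `confirmed` when its hits are significantly more frequent than fair
#' coin flips — two-sided exact binomial test of `hit_count` against
#' p = 0.5 at level `alpha`, Bonferroni-corrected over features, requiring
#' more hits than misses (`rule = "binomial"`, the canonical aggregation) —
#' or simply when the hit fraction exceeds 0.5 (`rule = "fraction"`).
#' All other features are `rejected` (no tentative state).
#'
#' @param x Feature tibble (features only) or a feature table with
#'   `subject_id`/`group` columns (stripped automatically).
#' @param y Binary class labels; taken from `x$group` when omitted.
#' @param n_iter Number of iterations (the reference analysis used 2000;
#'   defaults to 200 for desk-scale runs).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 100).
#' @param rule `"binomial"` (default) or `"fraction"`.
#' @param alpha Significance level of the binomial rule (default 0.01).
#' @return An object of class `boruta_report`: tibble with `feature`,
#'   `hit_count`, `hit_fraction`, `p_value`, `decision`, plus attributes
#'   `n_iterations`, `rule`, `alpha`.
#' @export
run_boruta <- function(x, y = NULL, n_iter = 200, seed = 1, num_trees = 100,
                       rule = c("binomial", "fraction"), alpha = 0.01) {
  rule <- match.arg(rule)
  if (n_iter < 1) abort("n_iter must be >= 1", class = "cardiotex_parameter_error")
  if (is.null(y)) {
    if (!"group" %in% names(x)) {
      abort("labels missing: supply y or a group column",
        class = "cardiotex_parameter_error")
    }
    y <- x$group
  }
  x <- dplyr::select(as_tibble(x),
    -dplyr::any_of(c("subject_id", "group")))
  hits <- rep(0L, ncol(x))
  for (it in seq_len(n_iter)) {
    hits <- hits + boruta_iteration(x, y, num_trees, child_seed(seed, it))
  }
  p_vals <- vapply(hits, function(h) binom.test(h, n_iter, 0.5)$p.value,
    numeric(1))
  confirmed <- if (rule == "binomial") {
    hits > n_iter / 2 & p_vals < alpha / ncol(x)
  } else {
    hits / n_iter > 0.5
  }
  out <- tibble(
    feature = names(x),
    hit_count = as.integer(hits),
    hit_fraction = hits / n_iter,
    p_value = p_vals,
    decision = ifelse(confirmed, "confirmed", "rejected")
  )
  structure(out,
    class = c("boruta_report", class(tibble())),
    n_iterations = n_iter, rule = rule, alpha = alpha
  )
}

#' @export
print.boruta_report <- function(x, ...) {
  cat("<boruta_report>", attr(x, "n_iterations"), "iterations,",
    sum(x$decision == "confirmed"), "of", nrow(x), "features confirmed\n")
  NextMethod()
}
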