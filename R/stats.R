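#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) skewness z-score and the Anscombe-Glynn
#' (1983) kurtosis z-score into the omnibus statistic
#' `K^2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires `n >= 20` (the kurtosis approximation is
#' unreliable below that).
#'
#' @param x Numeric vector (`n >= 20`).
#' @return List with `statistic` (K^2), `z_skewness`, `z_kurtosis`,
#'   `p_value`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20) {
    abort("D'Agostino-Pearson test requires n >= 20",
      class = "cardiotex_parameter_error")
  }
  d <- x - mean(x)
  m2 <- mean(d^2)
  g1 <- mean(d^3) / m2^1.5
  b2 <- mean(d^4) / m2^2

  # Skewness: D'Agostino's transformation to normality.
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # Kurtosis: Anscombe-Glynn transformation.
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x1 <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  inner <- (1 - 2 / a) / (1 + x1 * sqrt(2 / (a - 4)))
  z2 <- (1 - 2 / (9 * a) - sign(inner) * abs(inner)^(1 / 3)) *
    sqrt(9 * a / 2)

  k2 <- z1^2 + z2^2
  list(
    statistic = k2, z_skewness = z1, z_kurtosis = z2,
    p_value = pchisq(k2, df = 2, lower.tail = FALSE), n = n
  )
}

#' Pooled-variance Student t-test from group summaries
#'
#' Two-sided Student t-test reconstructed from the per-group mean, SD and
#' n (as printed in a descriptive table), with pooled variance and
#' `n1 + n2 - 2` degrees of freedom. It reproduces `t.test(var.equal =
#' TRUE)` exactly when the summaries derive from the raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`sd > 0`, `n >= 2`).
#' @return List with `t`, `df`, `p_value`.
#' @examples
#' ttest_summary(10.01, 2.7, 83, 8.15, 1.66, 75) # t = 5.15, p < 0.001
#' @export
ttest_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) < 0) || any(c(n1, n2) < 2)) {
    abort("need sd >= 0 and n >= 2 per group", class = "cardiotex_parameter_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_val <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t_val, df = df, p_value = 2 * pt(-abs(t_val), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (a thin validating wrapper over `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "cardiotex_parameter_error")
  }
  p.adjust(p, method = "BH")
}

#' Yates-corrected chi-squared test of a 2x2 table
#'
#' Pearson chi-squared test with continuity correction on the table
#' `rbind(c(a, b), c(c, d))` (rows = groups, columns = category yes/no).
#'
#' @param a,b,c,d Non-negative counts; all margins must be positive.
#' @return List with `statistic`, `p_value`.
#' @examples
#' chi2_test(35, 48, 45, 30)$p_value # ~0.038
#' @export
chi2_test <- function(a, b, c, d) {
  m <- rbind(c(a, b), c(c, d))
  if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("counts must be non-negative with positive margins",
      class = "cardiotex_parameter_error")
  }
  ct <- chisq.test(m, correct = TRUE)
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Per-feature group comparison and smile-plot coordinates
#'
#' For every feature of a raw (un-autoscaled) feature table: per-class
#' mean and SD, pooled Student t p-value, BH-FDR adjusted p, fold change
#' `FC = mean(HTN) / mean(NC)` (defined only when both class means are
#' positive), `log2(FC)`, `-log10(adjusted p)`, and the smile-plot flags
#' (`|FC| >= fc_cutoff` in either direction, adjusted p below `fdr_level`,
#' and their conjunction `flagged`).
#'
#' @param table Feature tibble with `group` and feature columns (raw scale).
#' @param fdr_level Adjusted-p threshold (default 0.05).
#' @param fc_cutoff Fold-change threshold; "two-fold" means
#'   `FC >= 2` or `FC <= 1/2` (default 2).
#' @return An object of class `smile_table` (a tibble, one row per
#'   feature).
#' @export
smile_table <- function(table, fdr_level = 0.05, fc_cutoff = 2) {
  feats <- feature_columns(table)
  is_htn <- table$group == "HTN"
  rows <- purrr::map_dfr(feats, function(f) {
    v <- table[[f]]
    ok <- !is.na(v)
    vh <- v[is_htn & ok]
    vn <- v[!is_htn & ok]
    p <- if (length(vh) >= 2 && length(vn) >= 2 && (sd(vh) > 0 || sd(vn) > 0)) {
      t.test(vh, vn, var.equal = TRUE)$p.value
    } else {
      NA_real_
    }
    tibble(
      feature = f,
      mean_htn = mean(vh), sd_htn = sd(vh),
      mean_nc = mean(vn), sd_nc = sd(vn),
      p_raw = p
    )
  })
  rows$p_adj <- bh_fdr(rows$p_raw)
  rows <- dplyr::mutate(rows,
    fold_change = ifelse(.data$mean_htn > 0 & .data$mean_nc > 0,
      .data$mean_htn / .data$mean_nc, NA_real_),
    log2_fc = log2(.data$fold_change),
    neg_log10_p = -log10(.data$p_adj),
    fc_defined = !is.na(.data$fold_change),
    fc_flag = !is.na(.data$fold_change) &
      (.data$fold_change >= fc_cutoff | .data$fold_change <= 1 / fc_cutoff),
    sig_flag = !is.na(.data$p_adj) & .data$p_adj < fdr_level,
    flagged = .data$fc_flag & .data$sig_flag
  )
  structure(rows,
    class = c("smile_table", class(tibble())),
    fdr_level = fdr_level, fc_cutoff = fc_cutoff
  )
}

#' Clinical baseline summary table
#'
#' Descriptive HTN-vs-NC comparison of the clinical covariates, mirroring
#' a baseline-characteristics table: continuous variables as mean +/- SD
#' with a pooled Student t p-value, categorical variables as count
#' (percentage, computed from the counts) with a Yates-corrected
#' chi-squared p-value.
#'
#' @param clinical Clinical tibble (`group`, `sex`, `age`, `bmi`,
#'   `diabetes`, `dyslipidemia`, `septum_width`).
#' @return Tibble with one row per variable: `variable`, `type`,
#'   `htn_summary`, `nc_summary`, `htn_value`, `nc_value` (mean or
#'   percentage), `p_value`.
#' @export
clinical_summary <- function(clinical) {
  is_htn <- clinical$group == "HTN"
  n1 <- sum(is_htn)
  n2 <- sum(!is_htn)
  cont_row <- function(var) {
    vh <- clinical[[var]][is_htn]
    vn <- clinical[[var]][!is_htn]
    tt <- ttest_summary(mean(vh), sd(vh), n1, mean(vn), sd(vn), n2)
    tibble(
      variable = var, type = "continuous",
      htn_summary = sprintf("%.2f ± %.2f", mean(vh), sd(vh)),
      nc_summary = sprintf("%.2f ± %.2f", mean(vn), sd(vn)),
      htn_value = mean(vh), nc_value = mean(vn), p_value = tt$p_value
    )
  }
  cat_row <- function(var, yes) {
    ch <- sum(clinical[[var]][is_htn] %in% yes)
    cn <- sum(clinical[[var]][!is_htn] %in% yes)
    ph <- round(100 * ch / n1, 2)
    pn <- round(100 * cn / n2, 2)
    tibble(
      variable = var, type = "categorical",
      htn_summary = sprintf("%d (%.2f%%)", ch, ph),
      nc_summary = sprintf("%d (%.2f%%)", cn, pn),
      htn_value = ph, nc_value = pn,
      p_value = chi2_test(ch, n1 - ch, cn, n2 - cn)$p_value
    )
  }
  dplyr::bind_rows(
    cat_row("sex", "F"),
    cont_row("age"),
    cat_row("dyslipidemia", c(TRUE, "TRUE")),
    cont_row("bmi"),
    cat_row("diabetes", c(TRUE, "TRUE")),
    cont_row("septum_width")
  )
}
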