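test_that("the omnibus normality statistic matches an independent implementation", {
  # expected values frozen from an independent implementation of the
  # D'Agostino (1970) / Anscombe-Glynn (1983) formulas
  x <- c(11.0265, 8.3734, 11.578, 12.0608, 6.7833, 7.7843, 11.5199, 10.076,
    10.2043, 8.755, 12.4004, 11.8994, 10.454, 13.1334, 11.232, 9.6151,
    12.1284, 9.1663, 11.8299, 11.0342, 10.9846, 9.7602, 12.7251, 10.0119,
    9.3091)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 1.4564790564690464, tolerance = 1e-8)
  expect_equal(r$p_value, 0.48275812448003763, tolerance = 1e-8)
  y <- (1:30)^1.5
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 5.064157813283076, tolerance = 1e-8)
  expect_equal(r2$p_value, 0.07949358863762432, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(19)), class = "cardiotex_parameter_error")
})

test_that("the normality test is calibrated under the null and powered against skew", {
  set.seed(71)
  p_null <- replicate(200, dagostino_pearson(rnorm(5000))$p_value)
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  p_exp <- replicate(20, dagostino_pearson(stats::rexp(200))$p_value)
  expect_gte(mean(p_exp < 0.01), 0.95)
})

test_that("summary t-test reproduces the published septum comparison and raw t", {
  r <- ttest_summary(10.01, 2.7, 83, 8.15, 1.66, 75)
  expect_equal(r$t, 5.15, tolerance = 1e-2)
  expect_equal(r$df, 156)
  expect_lt(r$p_value, 0.001)
  expect_equal(ttest_summary(5, 1, 10, 5, 1, 12)$t, 0)
  expect_equal(ttest_summary(5, 1, 10, 5, 1, 12)$p_value, 1)
  set.seed(72)
  a <- rnorm(30, 1); b <- rnorm(25)
  r2 <- ttest_summary(mean(a), sd(a), 30, mean(b), sd(b), 25)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "cardiotex_parameter_error")
  set.seed(73)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12)) # rank monotonicity
})

test_that("the 2x2 chi-squared test reproduces the published clinical p-values", {
  expect_lt(abs(chi2_test(35, 48, 45, 30)$p_value - 0.038), 5e-4)
  expect_lt(abs(chi2_test(18, 65, 4, 71)$p_value - 0.006), 5e-4)
  # row/column swap invariance
  a <- chi2_test(12, 20, 7, 30)
  expect_equal(chi2_test(7, 30, 12, 20)$statistic, a$statistic)
  expect_equal(chi2_test(20, 12, 30, 7)$statistic, a$statistic)
  expect_gt(chi2_test(20, 30, 20, 30)$p_value, 0.9)
  expect_error(chi2_test(0, 0, 5, 5), class = "cardiotex_parameter_error")
})

test_that("the smile table computes fold changes and flags as specified", {
  set.seed(74)
  n <- 60
  g <- rep(c("HTN", "NC"), each = n / 2)
  tbl <- tibble::tibble(
    group = g,
    up = rnorm(n, ifelse(g == "HTN", 4, 2), 0.3), # FC 2, strong
    flat = rnorm(n, 5, 0.5),
    negged = rnorm(n, ifelse(g == "HTN", -3, 2), 0.5) # FC undefined
  )
  sm <- smile_table(tbl)
  up <- sm[sm$feature == "up", ]
  expect_equal(up$fold_change, mean(tbl$up[g == "HTN"]) / mean(tbl$up[g == "NC"]))
  expect_equal(up$log2_fc, log2(up$fold_change))
  expect_equal(up$neg_log10_p, -log10(up$p_adj))
  expect_true(up$flagged)
  expect_false(sm$flagged[sm$feature == "flat"])
  expect_lt(abs(sm$log2_fc[sm$feature == "flat"]), 0.2)
  expect_false(sm$fc_defined[sm$feature == "negged"])
  expect_true(all(sm$p_adj >= sm$p_raw - 1e-12, na.rm = TRUE))
})

test_that("planted fold-change features are flagged, null features are not", {
  set.seed(75)
  hits <- replicate(10, {
    n <- 80
    g <- rep(c("HTN", "NC"), each = n / 2)
    x <- matrix(rnorm(n * 20, 10, 1), n, 20,
      dimnames = list(NULL, paste0("null", 1:20)))
    tbl <- tibble::as_tibble(x)
    tbl$planted1 <- rnorm(n, ifelse(g == "HTN", 30, 10), 2)
    tbl$planted2 <- rnorm(n, ifelse(g == "HTN", 4, 12), 1)
    tbl$group <- g
    sm <- smile_table(tbl)
    planted_ok <- all(sm$flagged[sm$feature %in% c("planted1", "planted2")])
    nulls_ok <- !any(sm$flagged[startsWith(sm$feature, "null")])
    planted_ok && nulls_ok
  })
  expect_gte(mean(hits), 0.9)
})

test_that("under the global null few features pass the FDR gate", {
  set.seed(76)
  frac_sig <- replicate(50, {
    n <- 40
    g <- rep(c("HTN", "NC"), each = n / 2)
    x <- matrix(rnorm(n * 30, 5), n, 30,
      dimnames = list(NULL, paste0("f", 1:30)))
    tbl <- dplyr::mutate(tibble::as_tibble(x), group = g)
    mean(smile_table(tbl)$sig_flag)
  })
  expect_lte(mean(frac_sig), 0.05)
})

test_that("the clinical baseline table reports counts, percentages and tests", {
  clin <- tibble::tibble(
    group = rep(c("HTN", "NC"), c(83, 75)),
    sex = c(rep("F", 35), rep("M", 48), rep("F", 45), rep("M", 30)),
    age = c(rnorm(83, 65.6, 10.2), rnorm(75, 55.6, 12.4)),
    bmi = c(rnorm(83, 28.4, 6.1), rnorm(75, 25.5, 4.9)),
    diabetes = c(rep(TRUE, 18), rep(FALSE, 65), rep(TRUE, 4), rep(FALSE, 71)),
    dyslipidemia = c(rep(TRUE, 18), rep(FALSE, 65), rep(TRUE, 10), rep(FALSE, 65)),
    septum_width = c(rnorm(83, 10, 2.7), rnorm(75, 8.2, 1.7))
  )
  tab <- clinical_summary(clin)
  expect_equal(tab$htn_value[tab$variable == "sex"], 42.17)
  expect_equal(tab$htn_value[tab$variable == "diabetes"], 21.69)
  expect_equal(tab$p_value[tab$variable == "sex"], 0.0376, tolerance = 1e-2)
  expect_equal(tab$p_value[tab$variable == "diabetes"], 0.0062, tolerance = 1e-1)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("continuous", "categorical") %in% tab$type))
})
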