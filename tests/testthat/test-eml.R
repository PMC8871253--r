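make_pred <- function(ids, groups, predicted, confidence) {
  tibble::tibble(subject_id = ids, group = groups, predicted = predicted,
    confidence = confidence, p_htn = ifelse(predicted == "HTN", confidence,
      1 - confidence))
}

test_that("the accuracy gate is strict and errors when nothing passes", {
  ids <- c("a", "b"); grp <- c("HTN", "NC")
  preds <- replicate(3, make_pred(ids, grp, c("HTN", "NC"), c(1, 1)),
    simplify = FALSE)
  zoo <- fake_zoo(c("m1", "m2", "m3"), c(0.59, 0.60, 0.61), preds)
  sel <- select_models(zoo, 0.6)
  expect_equal(sel$model, "m3")
  expect_equal(sel$weight, 0.61)
  zoo_all <- fake_zoo(c("m1", "m2"), c(0.7, 0.9), preds[1:2])
  expect_equal(nrow(select_models(zoo_all, 0.6)), 2)
  expect_error(select_models(zoo, 0.99), class = "cardiotex_no_model_error")
})

test_that("EML scores equal the hand-computed signed weighted sums", {
  # one model: acc 0.8, predicts HTN with confidence 1 -> score 0.8
  z1 <- fake_zoo("m1", 0.8, list(make_pred("a", "HTN", "HTN", 1)))
  s1 <- eml_scores(z1, select_models(z1, 0.6))
  expect_equal(s1$score, 0.8)
  # two models: 0.8 * 0.9 (HTN) - 0.7 * 0.6 (NC) = 0.30
  z2 <- fake_zoo(c("m1", "m2"), c(0.8, 0.7), list(
    make_pred("a", "HTN", "HTN", 0.9),
    make_pred("a", "HTN", "NC", 0.6)
  ))
  s2 <- eml_scores(z2, select_models(z2, 0.6))
  expect_equal(s2$score, 0.8 * 0.9 - 0.7 * 0.6)
  # unanimous NC with confidence 1 -> minus the summed accuracies
  z3 <- fake_zoo(c("m1", "m2"), c(0.9, 0.7), list(
    make_pred("a", "NC", "NC", 1),
    make_pred("a", "NC", "NC", 1)
  ))
  s3 <- eml_scores(z3, select_models(z3, 0.6))
  expect_equal(s3$score, -(0.9 + 0.7))
})

test_that("unanimous confident votes set the score sign, and weights only scale it", {
  set.seed(51)
  ids <- sprintf("s%02d", 1:20)
  grp <- rep(c("HTN", "NC"), 10)
  consensus <- sample(c("HTN", "NC"), 20, replace = TRUE)
  zoo <- fake_zoo(c("m1", "m2", "m3"), c(0.7, 0.8, 0.9), purrr::map(1:3,
    function(i) make_pred(ids, grp, consensus, rep(1, 20))))
  sel <- select_models(zoo, 0.6)
  sc <- eml_scores(zoo, sel)
  expect_equal(ifelse(sc$score > 0, "HTN", "NC"),
    consensus[match(sc$subject_id, ids)])
  # scaling all weights by c scales scores by c, AUC unchanged
  sel2 <- dplyr::mutate(sel, weight = weight * 3)
  sc2 <- eml_scores(zoo, sel2)
  expect_equal(sc2$score, 3 * sc$score)
  expect_equal(roc_delong(sc2$score, sc2$group)$auc,
    roc_delong(sc$score, sc$group)$auc)
})

test_that("the Youden cutoff matches exhaustive threshold search", {
  expect_equal(youden_cutoff(c(2, 3, 0, 1), c("HTN", "HTN", "NC", "NC")), 1.5)
  # identical score distributions: best achievable J is 0
  sc <- c(1, 2, 3, 1, 2, 3)
  lb <- c("HTN", "HTN", "HTN", "NC", "NC", "NC")
  ct <- youden_cutoff(sc, lb)
  m <- cardiotex:::confusion_at_cutoff(sc, lb, ct)
  expect_equal(m$sensitivity + m$specificity - 1, 0)
  set.seed(52)
  for (i in 1:25) {
    scores <- round(rnorm(30), 1) # ties likely
    labels <- sample(c("HTN", "NC"), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    ct <- youden_cutoff(scores, labels)
    m <- cardiotex:::confusion_at_cutoff(scores, labels, ct)
    expect_equal(m$sensitivity + m$specificity - 1,
      oracle_best_youden(scores, labels), tolerance = 1e-12)
  }
  expect_error(youden_cutoff(1:3, c("HTN", "HTN", "HTN")),
    class = "cardiotex_parameter_error")
})

test_that("DeLong AUC equals pair counting and its SE matches pROC", {
  expect_equal(roc_delong(c(5, 6, 1, 2), c("HTN", "HTN", "NC", "NC"))$auc, 1)
  set.seed(53)
  for (i in 1:100) {
    n <- sample(8:20, 1)
    scores <- round(rnorm(n), 1)
    labels <- c("HTN", "NC", sample(c("HTN", "NC"), n - 2, replace = TRUE))
    r <- roc_delong(scores, labels)
    expect_identical(r$auc, oracle_auc(scores, labels))
  }
  skip_if_not_installed("pROC")
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- rep(c("HTN", "NC"), 20)
    r <- roc_delong(scores, labels)
    proc <- suppressMessages(pROC::roc(labels, scores, levels = c("NC", "HTN"),
      direction = "<"))
    expect_equal(r$auc, as.numeric(pROC::auc(proc)), tolerance = 1e-12)
    expect_equal(r$se^2, as.numeric(pROC::var(proc)), tolerance = 1e-10)
  }
})

test_that("label permutation centers the AUC on one half", {
  set.seed(54)
  scores <- rnorm(40)
  labels <- rep(c("HTN", "NC"), 20)
  aucs <- replicate(50, roc_delong(scores, sample(labels))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("score-septum correlation matches the covariance formula and its null", {
  x <- 1:10
  r <- correlate_septum(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)
  set.seed(55)
  for (i in 1:10) {
    a <- rnorm(25); b <- rnorm(25)
    r <- correlate_septum(a, b)
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(r$r, manual, tolerance = 1e-12)
  }
  # null distribution at n = 47: |r| below the 5% critical value ~0.288
  rs <- replicate(200, correlate_septum(rnorm(47), rnorm(47))$r)
  expect_gte(mean(abs(rs) < 0.29), 0.90)
  expect_error(correlate_septum(c(1, 1, 1), c(1, 2, 3)),
    class = "cardiotex_parameter_error")
})

test_that("eml_report assembles a consistent ensemble summary", {
  tbl <- separable_table(n_per_class = 30, p = 5, shift = 3, seed = 56)
  parts <- split_cohort(tbl, 0.7, seed = 4)
  sc <- autoscale(parts$train, parts$test)
  zoo <- train_zoo(sc$train, sc$test, models = c("NB", "RF", "GBT", "SVM"),
    cv_folds = 3, tuning_budget = 1, num_trees = 50, seed = 5)
  clin <- tibble::tibble(subject_id = tbl$subject_id,
    septum_width = ifelse(tbl$group == "HTN", 10, 8) + rnorm(60))
  rep <- eml_report(zoo, 0.6, clin)
  expect_s3_class(rep, "eml_report")
  expect_equal(nrow(rep$scores), nrow(parts$test))
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  m <- cardiotex:::confusion_at_cutoff(rep$scores$score, rep$scores$group,
    rep$cutoff)
  expect_equal(rep$metrics$accuracy, m$accuracy)
  g <- glance(rep)
  expect_equal(g$auc, rep$auc)
  expect_equal(g$r_squared, rep$correlation$r_squared)
  expect_equal(nrow(tidy(rep)), nrow(parts$test))
})
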