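test_that("confusion counts are complete and validated", {
  expect_identical(confusion(c(1, 0), c(1, 0)),
                   c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  expect_identical(confusion(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                   c(tp = 0L, fp = 2L, fn = 2L, tn = 0L))
  set.seed(2)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    l <- rbinom(n, 1, 0.4); p <- rbinom(n, 1, 0.4)
    expect_identical(sum(confusion(l, p)), n)
  }
  expect_error(confusion(c(1, 2), c(0, 1)), "binary")
})

test_that("the metric panel matches hand-computed confusion values", {
  # TP 5, FP 5, FN 5, TN 85
  labels <- rep(c(1, 1, 0, 0), c(5, 5, 5, 85))
  preds <- rep(c(1, 0, 1, 0), c(5, 5, 5, 85))
  m <- compute_metrics(labels, preds)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$specificity, 85 / 90)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$f1_macro, (0.5 + 170 / 180) / 2, tolerance = 1e-12)
})

test_that("perfect prediction scores 1 on all seven metrics", {
  labels <- rep(c(0, 1), 50)
  probs <- ifelse(labels == 1, 0.9, 0.1)
  m <- compute_metrics(labels, labels, probs)
  expect_true(all(abs(as.numeric(m) - 1) < 1e-12))
})

test_that("anti-correlated probabilities give ROC-AUC below one half", {
  set.seed(9)
  labels <- rbinom(200, 1, 0.3)
  probs <- 1 - (0.6 * labels + 0.4 * runif(200))
  expect_lt(compute_metrics(labels, labels, probs)$roc_auc, 0.5)
})

test_that("all seven metrics agree with the brute-force oracle", {
  set.seed(14)
  for (i in 1:20) {
    n <- 120
    labels <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (length(unique(labels)) < 2) next
    probs <- stats::plogis(rnorm(n) + 1.2 * labels)
    preds <- as.integer(probs > runif(1, 0.3, 0.7))
    m <- compute_metrics(labels, preds, probs)
    o <- oracle_metrics(labels, preds, probs)
    for (nm in names(o)) {
      expect_equal(m[[nm]], o[[nm]], tolerance = 1e-9, label = nm)
    }
  }
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  labels <- rbinom(300, 1, 0.3)
  probs <- stats::plogis(rnorm(300) + labels)
  got <- compute_metrics(labels, classify(probs, 0.5), probs)$roc_auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("bootstrap intervals are seeded percentile intervals", {
  labels <- rep(c(0, 1), c(70, 30))
  probs <- ifelse(labels == 1, 0.9, 0.1)
  ci <- bootstrap_ci(labels, labels, probs, n_boot = 200, seed = 8)
  expect_identical(ci$conf_low[ci$metric == "accuracy"], 1)
  expect_identical(ci$conf_high[ci$metric == "accuracy"], 1)
  expect_true(all(ci$conf_low <= ci$estimate + 1e-12))
  expect_true(all(ci$conf_high >= ci$estimate - 1e-12))
  ci2 <- bootstrap_ci(labels, labels, probs, n_boot = 200, seed = 8)
  expect_identical(ci, ci2)
  expect_error(bootstrap_ci(labels, labels, probs, n_boot = 50), "100")
})

test_that("cross-validation builds equal stratified folds and is seeded", {
  co <- generate_cohort(cohort_config(100, prevalence = 0.2, seed = 40))
  fold <- ppcwatch:::stratified_folds(co$ppc, 5, seed = 2)
  expect_identical(unname(as.integer(table(fold))), rep(20L, 5))
  for (f in 1:5) expect_identical(sum(co$ppc[fold == f]), 4L)
  expect_identical(ppcwatch:::stratified_folds(co$ppc, 5, seed = 2), fold)
})

test_that("the cross-validated objective is deterministic and high when separable", {
  co <- generate_cohort(cohort_config(300, preset = "separable", seed = 41))
  obj1 <- crossval_objective(co, k = 3, fold_seed = 7,
                             encoder = tiny_encoder(),
                             training = tiny_training(), seed = 7)
  obj2 <- crossval_objective(co, k = 3, fold_seed = 7,
                             encoder = tiny_encoder(),
                             training = tiny_training(), seed = 7)
  expect_identical(obj1, obj2)
  expect_gt(obj1, 0.9)
})

test_that("random search returns the argmax of its trial log", {
  co <- generate_cohort(cohort_config(250, preset = "separable", seed = 42))
  space <- list(rf_trees = c(5L, 60L))
  res <- search_hyperparams(space, co, n_trials = 4, k = 2, seed = 3,
                            encoder = tiny_encoder(),
                            training = tiny_training())
  expect_identical(nrow(res$trials), 4L)
  expect_gte(res$best_objective, max(res$trials$objective, na.rm = TRUE))
  res2 <- search_hyperparams(space, co, n_trials = 4, k = 2, seed = 3,
                             encoder = tiny_encoder(),
                             training = tiny_training())
  expect_identical(res$trials, res2$trials)
  expect_error(search_hyperparams(list(bogus = 1:2), co), "unknown search")
})

test_that("the ablation grid has four arms sharing seeds and splits", {
  co <- generate_cohort(cohort_config(400, preset = "separable", seed = 43))
  ab <- run_ablation(co, seeds = 1, encoder = tiny_encoder(),
                     training = tiny_training())
  expect_identical(nrow(ab), 4L)
  expect_setequal(ab$arm, c("full", "no_shap", "no_imbalance", "baseline"))
  expect_true(all(ppcwatch:::metric_names() %in% names(ab)))
  detail <- attr(ab, "detail")
  expect_identical(nrow(detail), 4L)
  expect_length(attr(ab, "failed"), 0)
  long <- tidy(ab)
  expect_identical(nrow(long), 28L)
})
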