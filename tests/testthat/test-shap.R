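test_that("the weight formula w = 1 + lambda * imp^gamma is exact", {
  w <- compute_feature_weights(c(a = 0, b = 1, c = 0.5))
  expect_identical(w$w[w$feature == "a"], 1)
  expect_lt(abs(w$w[w$feature == "b"] - 1.27), 1e-12)
  expect_lt(abs(w$w[w$feature == "c"] -
                  (1 + 0.27 * exp(0.82 * log(0.5)))), 1e-12)
  # zero importance stays at 1 for any parameters
  for (lam in c(0, 0.5, 2)) {
    expect_identical(compute_feature_weights(c(x = 0), lam, 1.7)$w, 1)
  }
})

test_that("weights are bounded, monotone in importance, linear in lambda", {
  set.seed(7)
  for (rep in 1:20) {
    imp <- sort(runif(10))
    lam <- runif(1, 0, 2); gam <- runif(1, 0.1, 3)
    w <- compute_feature_weights(imp, lam, gam)$w
    expect_true(all(w >= 1 & w <= 1 + lam + 1e-12))
    expect_true(all(diff(w) >= 0))
    w2 <- compute_feature_weights(imp, 2 * lam, gam)$w
    expect_equal(w2 - 1, 2 * (w - 1), tolerance = 1e-12)
  }
  expect_error(compute_feature_weights(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(compute_feature_weights(0.5, lambda_ = -1), "lambda")
  expect_error(compute_feature_weights(0.5, gamma_ = 0), "gamma")
})

test_that("normalize_importance divides by the maximum", {
  expect_identical(normalize_importance(c(2, 1, 0)), c(1, 0.5, 0))
  expect_identical(normalize_importance(c(3, 3)), c(1, 1))
  expect_warning(z <- normalize_importance(c(0, 0)), "zero")
  expect_identical(z, c(0, 0))
  expect_error(normalize_importance(c(-1, 2)), "non-negative")
})

test_that("preliminary forest fitting is seeded and validates its input", {
  co <- generate_cohort(cohort_config(300, preset = "separable", seed = 8))
  coded <- encode_categoricals(co)[schema_features(ppc_schema())]
  a <- fit_preliminary_rf(coded, co$ppc, seed = 5)
  b <- fit_preliminary_rf(coded, co$ppc, seed = 5)
  expect_identical(predict(a, coded), predict(b, coded))
  # separable preset: training discrimination is near perfect
  expect_gt(ppcwatch:::roc_auc_value(co$ppc, predict(a, coded)), 0.95)
  expect_error(fit_preliminary_rf(coded[0, ], integer(0)), "empty")
  expect_error(fit_preliminary_rf(coded, rep(1L, nrow(coded))), "both classes")
})

test_that("TreeSHAP satisfies local accuracy against the forest prediction", {
  co <- generate_cohort(cohort_config(250, seed = 10))
  coded <- encode_categoricals(co)[schema_features(ppc_schema())]
  rf <- fit_preliminary_rf(coded, co$ppc, seed = 2)
  sv <- shap_values(rf)
  expect_true(all(sv$phi == sv$phi))  # finite
  recon <- rowSums(sv$phi) + sv$base
  expect_lt(max(abs(recon - predict(rf, coded))), 1e-6)
})

test_that("TreeSHAP equals brute-force Shapley enumeration on small trees", {
  set.seed(42)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80), x3 = rnorm(80))
  y <- as.integer(d$x1 + 0.8 * d$x2 > 0)
  rf <- fit_preliminary_rf(d, y, num_trees = 4, max_depth = 3, seed = 9)
  fr <- ppcwatch:::extract_forest(rf$rf)
  cover <- ppcwatch:::forest_covers_cpp(fr$left, fr$right, fr$feature,
                                        fr$threshold, fr$tree_start,
                                        rf$x_train)
  X <- as.matrix(d[1:6, ])
  res <- ppcwatch:::treeshap_forest_cpp(fr$left, fr$right, fr$feature,
                                        fr$threshold, fr$value, cover,
                                        fr$tree_start, 3L, X)
  for (i in 1:6) {
    expect_lt(max(abs(oracle_shapley(fr, cover, X[i, ], 3) - res$phi[i, ])),
              1e-9)
  }
})

test_that("mean-|SHAP| ranks planted signal first and pure noise last", {
  firsts <- 0; noise_last <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 400
    d <- data.frame(strong = rnorm(n), weak = rnorm(n), noise = rnorm(n))
    y <- as.integer(1.5 * d$strong + 0.5 * d$weak + rnorm(n) > 0)
    rf <- fit_preliminary_rf(d, y, seed = s)
    imp <- compute_mean_abs_shap(rf)
    ord <- names(imp)[order(imp, decreasing = TRUE)]
    if (ord[1] == "strong") firsts <- firsts + 1
    if (ord[3] == "noise") noise_last <- noise_last + 1
  }
  expect_gte(firsts, 9)
  expect_gte(noise_last, 9)
})

test_that("fold-averaged importance is the mean of per-fold importances", {
  co <- generate_cohort(cohort_config(200, seed = 3))
  coded <- encode_categoricals(co)[schema_features(ppc_schema())]
  m1 <- fit_preliminary_rf(coded[1:100, ], co$ppc[1:100], seed = 1)
  m2 <- fit_preliminary_rf(coded[101:200, ], co$ppc[101:200], seed = 2)
  avg <- compute_mean_abs_shap(list(m1, m2))
  expect_equal(avg, (compute_mean_abs_shap(m1) + compute_mean_abs_shap(m2)) / 2,
               tolerance = 1e-12)
})

test_that("apply_weights scales inputs and is the identity at lambda 0", {
  co <- generate_cohort(cohort_config(100, seed = 12))
  st <- fit_normalization(co)
  input <- build_encoder_input(co, st)
  feats <- c(input$num_features, input$cat_features)
  imp <- stats::setNames(rep(0.5, length(feats)), feats)
  imp[["PR_max"]] <- 1

  w0 <- suppressWarnings(compute_feature_weights(
    stats::setNames(rep(0, length(feats)), feats), 0))
  same <- apply_weights(input, w0)
  expect_identical(same$num, input$num)
  expect_identical(same$cat_w, rep(1, length(input$cat_features)))

  w <- compute_feature_weights(imp)
  scaled <- apply_weights(input, w)
  j <- match("PR_max", input$num_features)
  expect_equal(scaled$num[, j], input$num[, j] * 1.27, tolerance = 1e-12)
  other <- match("Age", input$num_features)
  expect_equal(scaled$num[, other],
               input$num[, other] * w$w[w$feature == "Age"],
               tolerance = 1e-12)

  expect_error(apply_weights(input, w[1:5, ]), "do not cover")
})
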