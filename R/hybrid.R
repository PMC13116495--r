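#' Fit the random-forest classification head on latent representations
#'
#' @param latents numeric matrix of encoder latents (n x hidden2).
#' @param labels binary labels.
#' @param n_trees,max_depth forest size (tuned defaults 200 and 10).
#' @param balanced use inverse-frequency class weights in the splitting
#'   criterion (default `TRUE`).
#' @param seed integer RNG seed.
#' @return a `ppc_rf_head` object.
#' @export
fit_rf_head <- function(latents, labels, n_trees = 200, max_depth = 10,
                        balanced = TRUE, seed = 1) {
  labels <- as_binary(labels, "labels")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  df <- as.data.frame(latents)
  names(df) <- paste0("L", seq_len(ncol(df)))
  df$.ppc_y <- factor(labels, levels = c(0, 1))
  cw <- if (balanced) {
    tab <- table(df$.ppc_y)
    as.numeric(sum(tab) / (2 * tab))
  } else NULL
  rf <- ranger::ranger(dependent.variable.name = ".ppc_y", data = df,
                       num.trees = n_trees, max.depth = max_depth,
                       probability = TRUE, class.weights = cw, seed = seed,
                       num.threads = 1)
  structure(list(rf = rf, width = ncol(latents)), class = "ppc_rf_head")
}

#' @export
predict.ppc_rf_head <- function(object, latents, ...) {
  if (ncol(latents) != object$width) {
    stop("latent width does not match the fitted head", call. = FALSE)
  }
  df <- as.data.frame(latents)
  names(df) <- paste0("L", seq_len(ncol(df)))
  p <- predict(object$rf, df, num.threads = 1)$predictions
  unname(p[, "1"])
}

#' Optimize the decision threshold on validation data
#'
#' Scans a finite grid of candidate thresholds -- the midpoints between
#' consecutive sorted unique validation probabilities, plus 0.5 -- which is
#' exhaustive over all achievable confusion matrices. The default
#' criterion is positive-class F-beta (beta = 1, i.e. F1); ties are broken
#' toward the larger threshold (favoring specificity). The alternative
#' `"balance"` criterion maximizes the smaller of sensitivity and
#' specificity.
#'
#' @param probs validation probabilities.
#' @param labels validation labels (both classes present).
#' @param criterion `"f1"` (default) or `"balance"`.
#' @param beta F-beta weight for the `"f1"` criterion (default 1).
#' @return the selected threshold (scalar in (0, 1)); a degenerate
#'   probability vector (all values equal) returns 0.5 with a warning.
#' @export
optimize_threshold <- function(probs, labels, criterion = c("f1", "balance"),
                               beta = 1) {
  criterion <- match.arg(criterion)
  labels <- as_binary(labels, "labels")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the validation labels",
         call. = FALSE)
  }
  u <- sort(unique(probs))
  if (length(u) == 1L) {
    warning("all probabilities identical; returning threshold 0.5")
    return(0.5)
  }
  cand <- sort(unique(c((u[-1] + u[-length(u)]) / 2, 0.5)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  score <- vapply(cand, function(t) {
    pred <- as.integer(probs > t)
    tp <- sum(pred == 1L & labels == 1L)
    fp <- sum(pred == 1L & labels == 0L)
    if (criterion == "f1") {
      den <- (1 + beta^2) * tp + beta^2 * (n_pos - tp) + fp
      if (den == 0) 0 else (1 + beta^2) * tp / den
    } else {
      sens <- tp / n_pos
      spec <- (n_neg - fp) / n_neg
      min(sens, spec)
    }
  }, numeric(1))
  best <- max(score)
  cand[max(which(score == best))]  # tie -> larger threshold
}

#' Threshold a probability vector
#'
#' A case is predicted positive iff its probability strictly exceeds the
#' decision threshold.
#'
#' @param probs probabilities in `[0, 1]`.
#' @param threshold decision threshold in (0, 1).
#' @return integer vector of 0/1 predictions.
#' @export
#' @examples
#' classify(c(0.6, 0.517, 0.2), threshold = 0.517)
classify <- function(probs, threshold) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  as.integer(probs > threshold)
}

#' Fit the hybrid PPC risk classifier
#'
#' End-to-end training: schema validation, derived-bin regeneration, an
#' internal stratified train/validation split, preliminary-forest SHAP
#' importance converted to input-scaling weights \eqn{w = 1 + \lambda
#' imp^\gamma}, imbalance-aware encoder training, a random-forest head on
#' the latent representations, and decision-threshold calibration on the
#' validation split.
#'
#' Setting `imbalance = FALSE` switches off the whole imbalance suite
#' (positive loss weight, weighted sampler, balanced forest, tuned
#' threshold -> fixed 0.5); `use_shap_weights = FALSE` forces all input
#' weights to 1. These two switches define the ablation arms.
#'
#' @param data training cohort tibble (with label column `ppc`).
#' @param encoder an [encoder_config()].
#' @param training a [training_config()].
#' @param lambda,gamma importance-weighting parameters (tuned defaults
#'   0.27, 0.82).
#' @param use_shap_weights apply SHAP-derived input weights (default
#'   `TRUE`).
#' @param imbalance apply the imbalance-handling suite (default `TRUE`).
#' @param rf_trees,rf_depth forest-head size (defaults 200, 10).
#' @param prelim_trees,prelim_depth preliminary-forest size (defaults
#'   100, 6).
#' @param valid_fraction fraction of `data` held out internally for early
#'   stopping and threshold calibration (default 0.2).
#' @param threshold_criterion `"f1"` or `"balance"` (see
#'   [optimize_threshold()]).
#' @param schema schema tibble.
#' @param seed master seed controlling the split, the forests, and the
#'   encoder initialization/sampling.
#' @return a `ppc_model` object; see [predict.ppc_model()].
#' @export
ppc_fit <- function(data, encoder = encoder_config(),
                    training = training_config(), lambda = 0.27,
                    gamma = 0.82, use_shap_weights = TRUE, imbalance = TRUE,
                    rf_trees = 200, rf_depth = 10, prelim_trees = 100,
                    prelim_depth = 6, valid_fraction = 0.2,
                    threshold_criterion = "f1", schema = ppc_schema(),
                    seed = 1) {
  data <- derive_bins(tibble::as_tibble(data))
  issues <- validate_schema(data, schema)
  if (nrow(issues)) {
    stop("training data fails schema validation (",
         nrow(issues), " issue(s)); see validate_schema()", call. = FALSE)
  }
  if (!"ppc" %in% names(data)) stop("missing label column `ppc`", call. = FALSE)

  if (!imbalance) {
    training$pos_weight <- 1
    training$sampler <- "plain"
  }
  encoder$seed <- seed
  training$seed <- seed + 1L

  parts <- split_cohort(data, test_fraction = valid_fraction,
                        stratified = TRUE, seed = seed + 2L)
  tr_dat <- parts$train; va_dat <- parts$test
  y_tr <- tr_dat$ppc; y_va <- va_dat$ppc

  stats <- fit_normalization(tr_dat, schema)
  feats <- schema$name

  if (use_shap_weights && lambda > 0) {
    coded <- encode_categoricals(tr_dat, schema)[feats]
    prelim <- fit_preliminary_rf(coded, y_tr, num_trees = prelim_trees,
                                 max_depth = prelim_depth, seed = seed + 3L)
    raw <- compute_mean_abs_shap(prelim)
    imp <- normalize_importance(raw)
    weights <- compute_feature_weights(imp, lambda, gamma, raw = raw)
  } else {
    imp <- stats::setNames(rep(0, length(feats)), feats)
    weights <- suppressWarnings(compute_feature_weights(imp, 0, gamma))
  }

  in_tr <- apply_weights(build_encoder_input(tr_dat, stats, schema), weights)
  in_va <- apply_weights(build_encoder_input(va_dat, stats, schema), weights)

  enc_fit <- train_encoder(in_tr, y_tr, in_va, y_va, encoder, training)

  lat_tr <- extract_latents(enc_fit, in_tr)
  head_fit <- fit_rf_head(lat_tr, y_tr, n_trees = rf_trees,
                          max_depth = rf_depth, balanced = imbalance,
                          seed = seed + 4L)

  va_probs <- predict(head_fit, extract_latents(enc_fit, in_va))
  threshold <- if (imbalance) {
    tryCatch(optimize_threshold(va_probs, y_va,
                                criterion = threshold_criterion),
             warning = function(w) 0.5)
  } else 0.5

  structure(list(schema = schema, stats = stats, weights = weights,
                 encoder_fit = enc_fit, head = head_fit,
                 threshold = threshold, imbalance = imbalance,
                 use_shap_weights = use_shap_weights,
                 lambda = lambda, gamma = gamma, seed = seed,
                 val_auroc = roc_auc_value(y_va, va_probs),
                 n_train = nrow(tr_dat), n_valid = nrow(va_dat)),
            class = "ppc_model")
}

#' Predicted PPC probabilities for a cohort
#'
#' Runs the full inference chain (validation, normalization with training
#' statistics, importance weighting, encoder latents, forest head) and
#' returns one probability per patient, row-aligned with the input.
#'
#' @param model a fitted `ppc_model`.
#' @param data cohort tibble; must pass schema validation.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, data) {
  stopifnot(inherits(model, "ppc_model"))
  data <- derive_bins(tibble::as_tibble(data))
  issues <- validate_schema(data, model$schema)
  if (nrow(issues)) {
    stop("data fails schema validation (", nrow(issues),
         " issue(s)); see validate_schema()", call. = FALSE)
  }
  input <- apply_weights(build_encoder_input(data, model$stats, model$schema),
                         model$weights)
  predict(model$head, extract_latents(model$encoder_fit, input))
}

#' Predict method for hybrid PPC models
#'
#' @param object a fitted `ppc_model`.
#' @param data cohort tibble.
#' @param ... unused.
#' @return tibble with `.pred_prob` and `.pred_class` (0/1 at the model's
#'   calibrated threshold).
#' @export
predict.ppc_model <- function(object, data, ...) {
  probs <- predict_proba(object, data)
  tibble::tibble(.pred_prob = probs,
                 .pred_class = classify(probs, object$threshold))
}

#' @export
print.ppc_model <- function(x, ...) {
  cat("Hybrid PPC risk model\n")
  cat("  encoder: ", x$encoder_fit$enc$hidden1, "->",
      x$encoder_fit$enc$hidden2, " (dropout ",
      x$encoder_fit$enc$dropout, ")\n", sep = "")
  cat("  forest head:", x$head$rf$num.trees, "trees\n")
  cat("  importance weighting: lambda =", x$lambda, "gamma =", x$gamma, "\n")
  cat("  decision threshold:", round(x$threshold, 4), "\n")
  cat("  validation AUROC:", round(x$val_auroc, 4), "\n")
  invisible(x)
}

#' @export
tidy.ppc_model <- function(x, ...) {
  tibble::as_tibble(x$weights)
}

#' @export
glance.ppc_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_valid = x$n_valid,
                 threshold = x$threshold, val_auroc = x$val_auroc,
                 lambda = x$lambda, gamma = x$gamma,
                 imbalance = x$imbalance,
                 best_epoch = x$encoder_fit$best_epoch,
                 pos_weight = x$encoder_fit$pos_weight)
}

#' Training-history plot for the encoder inside a fitted model
#'
#' @param model a `ppc_model` or `ppc_encoder_fit`.
#' @return a ggplot of per-epoch loss and validation AUROC.
#' @export
plot_training_history <- function(model) {
  h <- if (inherits(model, "ppc_model")) model$encoder_fit$history else model$history
  d <- tidyr::pivot_longer(h, c("loss", "val_auroc"), names_to = "series")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
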