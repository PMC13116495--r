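#' Evaluate a fitted model on a test cohort
#'
#' Convenience wrapper: predicts, thresholds at the model's calibrated
#' decision threshold, and returns the seven-metric panel, optionally with
#' percentile bootstrap intervals.
#'
#' @param model a fitted `ppc_model`.
#' @param data test cohort tibble (label column `ppc`).
#' @param ci compute bootstrap intervals (default `FALSE`).
#' @param n_boot,seed bootstrap settings (see [bootstrap_ci()]).
#' @return a `ppc_metrics` row, or a `ppc_metrics_ci` tibble when
#'   `ci = TRUE`.
#' @export
ppc_evaluate <- function(model, data, ci = FALSE, n_boot = 1000, seed = 1) {
  probs <- predict_proba(model, data)
  preds <- classify(probs, model$threshold)
  if (ci) {
    bootstrap_ci(data$ppc, preds, probs, n_boot = n_boot, seed = seed)
  } else {
    compute_metrics(data$ppc, preds, probs)
  }
}

# stratified fold assignment, deterministic under seed
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    rows <- sample(which(labels == cl))
    if (length(rows) < k) {
      stop("class ", cl, " has fewer patients than folds", call. = FALSE)
    }
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

#' Cross-validated AUROC objective
#'
#' Mean validation AUROC over k stratified folds of the full pipeline fit
#' with the supplied arguments. The fold assignment is fixed by
#' `fold_seed`, so different configurations evaluated against the same
#' `fold_seed` see identical folds and are directly comparable.
#'
#' @param data cohort tibble (label column `ppc`).
#' @param k number of folds (default 5).
#' @param fold_seed seed fixing the fold assignment.
#' @param ... arguments forwarded to [ppc_fit()].
#' @return mean held-out-fold AUROC (scalar).
#' @export
crossval_objective <- function(data, k = 5, fold_seed = 1, ...) {
  fold <- stratified_folds(data$ppc, k, fold_seed)
  aucs <- vapply(seq_len(k), function(f) {
    fit <- ppc_fit(data[fold != f, , drop = FALSE], ...)
    probs <- predict_proba(fit, data[fold == f, , drop = FALSE])
    auc <- roc_auc_value(as_binary(data$ppc[fold == f], "labels"), probs)
    if (!is.finite(auc)) stop("fold ", f, " has a single class", call. = FALSE)
    auc
  }, numeric(1))
  mean(aucs)
}

search_dimensions <- function() {
  list(encoder = c("hidden1", "hidden2", "dropout", "embedding_dim"),
       training = c("batch_size", "learning_rate", "loss_kind",
                    "focal_alpha", "focal_gamma"),
       direct = c("rf_trees", "rf_depth", "lambda", "gamma"))
}

sample_dimension <- function(spec) {
  if (is.list(spec) && !is.null(spec$min)) {
    if (isTRUE(spec$log)) {
      exp(stats::runif(1, log(spec$min), log(spec$max)))
    } else {
      stats::runif(1, spec$min, spec$max)
    }
  } else {
    spec[[sample.int(length(spec), 1)]]
  }
}

#' Random search over the hyperparameter space
#'
#' Seeded random search over the declared space: each dimension is either
#' a vector of choices (sampled uniformly) or a `list(min =, max =, log =)`
#' continuous range. The objective is the k-fold cross-validated AUROC of
#' the full pipeline; every trial sees the same folds. Trials that error
#' are logged with an `NA` objective.
#'
#' @param space named list of dimensions; valid names are `hidden1`,
#'   `hidden2`, `dropout`, `embedding_dim`, `batch_size`, `learning_rate`,
#'   `loss_kind`, `focal_alpha`, `focal_gamma`, `rf_trees`, `rf_depth`,
#'   `lambda`, `gamma`.
#' @param data cohort tibble.
#' @param n_trials number of trials (default 50).
#' @param k folds for the objective (default 5).
#' @param seed seed for the trial sequence and the shared folds.
#' @param ... further fixed arguments for [ppc_fit()].
#' @return list with `best_config` (named list), `best_objective`, and
#'   `trials` (tibble of every trial's configuration and objective).
#' @export
search_hyperparams <- function(space, data, n_trials = 50, k = 5, seed = 1,
                               ...) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  dims <- search_dimensions()
  valid <- unlist(dims, use.names = FALSE)
  bad <- setdiff(names(space), valid)
  if (length(bad)) {
    stop("unknown search dimension(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  configs <- lapply(seq_len(n_trials), function(i) {
    lapply(space, sample_dimension)
  })
  fixed <- list(...)
  base_enc <- if (!is.null(fixed$encoder)) fixed$encoder else encoder_config()
  base_tr <- if (!is.null(fixed$training)) fixed$training else training_config()
  fixed$encoder <- fixed$training <- NULL
  objectives <- vapply(configs, function(cfg) {
    enc <- base_enc
    enc[intersect(names(cfg), dims$encoder)] <-
      cfg[intersect(names(cfg), dims$encoder)]
    tr <- base_tr
    tr[intersect(names(cfg), dims$training)] <-
      cfg[intersect(names(cfg), dims$training)]
    direct <- cfg[intersect(names(cfg), dims$direct)]
    args <- c(list(data = data, k = k, fold_seed = seed, encoder = enc,
                   training = tr),
              direct, fixed)
    tryCatch(do.call(crossval_objective, args),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(objectives))) {
    stop("all trials failed; inspect the space", call. = FALSE)
  }
  trials <- dplyr::bind_cols(
    tibble::tibble(trial = seq_len(n_trials), objective = objectives),
    dplyr::bind_rows(lapply(configs, function(cfg) {
      tibble::as_tibble(lapply(cfg, function(v) {
        if (is.character(v)) v else as.numeric(v)
      }))
    })))
  best <- which.max(objectives)
  list(best_config = configs[[best]], best_objective = objectives[[best]],
       trials = trials)
}

ablation_arms <- function() {
  tibble::tribble(
    ~arm,           ~use_shap_weights, ~imbalance,
    "full",          TRUE,              TRUE,
    "no_shap",       FALSE,             TRUE,
    "no_imbalance",  TRUE,              FALSE,
    "baseline",      FALSE,             FALSE)
}

#' Component ablation of the hybrid pipeline
#'
#' Trains four configurations on identical splits for every seed: the full
#' model; without SHAP importance weighting (all input weights 1); without
#' imbalance handling (plain loss, plain sampler, unbalanced forest, fixed
#' 0.5 threshold); and the baseline with both removed. Test metrics are
#' averaged over seeds.
#'
#' @param data cohort tibble.
#' @param seeds integer vector of seeds (>= 1 seed).
#' @param test_fraction held-out test fraction per seed (default 0.2).
#' @param ... further arguments for [ppc_fit()].
#' @return a `ppc_ablation` tibble: one row per arm with mean metrics;
#'   per-seed results in `attr(, "detail")`, failed arms flagged in
#'   `attr(, "failed")`.
#' @export
run_ablation <- function(data, seeds = 1:5, test_fraction = 0.2, ...) {
  if (!length(seeds)) stop("at least one seed required", call. = FALSE)
  arms <- ablation_arms()
  detail <- list()
  failed <- character()
  for (s in seeds) {
    parts <- split_cohort(data, test_fraction = test_fraction,
                          stratified = TRUE, seed = s)
    for (i in seq_len(nrow(arms))) {
      res <- tryCatch({
        fit <- ppc_fit(parts$train,
                       use_shap_weights = arms$use_shap_weights[i],
                       imbalance = arms$imbalance[i], seed = s, ...)
        m <- ppc_evaluate(fit, parts$test)
        dplyr::mutate(tibble::as_tibble(m), arm = arms$arm[i], seed = s,
                      .before = 1)
      }, error = function(e) {
        failed <<- c(failed, paste0(arms$arm[i], "/seed", s, ": ",
                                    conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) detail[[length(detail) + 1L]] <- res
    }
  }
  detail <- dplyr::bind_rows(detail)
  out <- detail |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_names()),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_seeds = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$arm, arms$arm))
  attr(out, "detail") <- detail
  attr(out, "failed") <- failed
  class(out) <- c("ppc_ablation", class(out))
  out
}

#' @export
tidy.ppc_ablation <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::all_of(metric_names()),
                      names_to = "metric", values_to = "estimate")
}

#' @export
autoplot.ppc_ablation <- function(object, ...) {
  d <- tidy.ppc_ablation(object)
  d$arm <- factor(d$arm, levels = ablation_arms()$arm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Ablation study") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
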