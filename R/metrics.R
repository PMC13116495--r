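#' Confusion-matrix counts
#'
#' @param labels observed binary labels (0/1 or logical).
#' @param preds predicted binary labels.
#' @return named integer vector `c(tp, fp, fn, tn)`; the counts sum to the
#'   number of cases.
#' @export
confusion <- function(labels, preds) {
  labels <- as_binary(labels, "labels")
  preds <- as_binary(preds, "preds")
  if (length(labels) != length(preds)) {
    stop("`labels` and `preds` have different lengths", call. = FALSE)
  }
  c(tp = sum(labels == 1L & preds == 1L),
    fp = sum(labels == 0L & preds == 1L),
    fn = sum(labels == 1L & preds == 0L),
    tn = sum(labels == 0L & preds == 0L))
}

as_binary <- function(x, what) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || !all(x %in% c(0, 1))) {
    stop("`", what, "` must be binary (0/1)", call. = FALSE)
  }
  as.integer(x)
}

# rank-based ROC-AUC (Mann-Whitney statistic; ties get average rank, which
# is the trapezoidal-rule value)
roc_auc_value <- function(labels, probs) {
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# step-wise (average-precision) PR-AUC: precision is held constant between
# consecutive recall points, never linearly interpolated
pr_auc_value <- function(labels, probs) {
  n1 <- sum(labels == 1L)
  if (n1 == 0L || n1 == length(labels)) return(NA_real_)
  ord <- order(probs, decreasing = TRUE)
  l <- labels[ord]; p <- probs[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(p[-1] != p[-length(p)], TRUE)  # last index at each threshold
  prec <- (tp / (tp + fp))[keep]
  rec <- (tp / n1)[keep]
  sum(diff(c(0, rec)) * prec)
}

f1_class <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  if (den == 0) return(0)
  2 * tp / den
}

#' Compute the seven-metric evaluation panel
#'
#' Point estimates of precision, recall (sensitivity), accuracy, macro F1,
#' ROC-AUC, PR-AUC and specificity. ROC-AUC is the Mann-Whitney statistic
#' (trapezoidal rule with tie handling); PR-AUC uses step-wise precision
#' interpolation (average precision). With single-class labels the two AUC
#' metrics are `NA`; the confusion-matrix metrics are still computed.
#' Conventions for empty denominators: precision is 0 when nothing is
#' predicted positive, and a per-class F1 is 0 when its denominator is 0.
#'
#' @param labels observed binary labels.
#' @param preds predicted binary labels.
#' @param probs predicted positive-class probabilities (needed for the AUC
#'   metrics; may be `NULL`).
#' @return one-row tibble (class `ppc_metrics`) with columns `precision`,
#'   `recall`, `accuracy`, `f1_macro`, `roc_auc`, `pr_auc`, `specificity`.
#' @export
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(1, 0, 0, 0), c(.9, .2, .4, .1))
compute_metrics <- function(labels, preds, probs = NULL) {
  cm <- confusion(labels, preds)
  labels <- as_binary(labels, "labels")
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  specificity <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  accuracy <- (tp + tn) / sum(cm)
  f1m <- (f1_class(tp, fp, fn) + f1_class(tn, fn, fp)) / 2
  roc <- pr <- NA_real_
  if (!is.null(probs)) {
    stopifnot(length(probs) == length(labels))
    roc <- roc_auc_value(labels, probs)
    pr <- pr_auc_value(labels, probs)
  }
  out <- tibble::tibble(precision = precision, recall = recall,
                        accuracy = accuracy, f1_macro = f1m,
                        roc_auc = roc, pr_auc = pr,
                        specificity = specificity)
  class(out) <- c("ppc_metrics", class(out))
  out
}

metric_names <- function() {
  c("precision", "recall", "accuracy", "f1_macro", "roc_auc", "pr_auc",
    "specificity")
}

#' Percentile bootstrap confidence intervals for the metric panel
#'
#' Case resampling with replacement keeps each patient's (label, pred,
#' prob) triple paired. A resample that loses one class is redrawn (at most
#' 100 retries per resample, then an error). Intervals are percentile
#' 2.5%/97.5%.
#'
#' @param labels,preds,probs as in [compute_metrics()].
#' @param n_boot number of bootstrap resamples (>= 100; default 1000).
#' @param seed integer RNG seed.
#' @param conf_level confidence level (default 0.95).
#' @return tibble (class `ppc_metrics_ci`) with columns `metric`,
#'   `estimate`, `conf_low`, `conf_high`.
#' @export
bootstrap_ci <- function(labels, preds, probs, n_boot = 1000, seed = 1,
                         conf_level = 0.95) {
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  labels <- as_binary(labels, "labels")
  point <- compute_metrics(labels, preds, probs)
  set.seed(seed)
  n <- length(labels)
  boot <- matrix(NA_real_, n_boot, length(metric_names()),
                 dimnames = list(NULL, metric_names()))
  for (b in seq_len(n_boot)) {
    for (try in seq_len(100)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      if (try == 100) stop("could not draw a two-class resample", call. = FALSE)
    }
    m <- compute_metrics(labels[idx], preds[idx],
                         if (is.null(probs)) NULL else probs[idx])
    boot[b, ] <- as.numeric(m[1, metric_names()])
  }
  alpha <- (1 - conf_level) / 2
  out <- tibble::tibble(
    metric = metric_names(),
    estimate = as.numeric(point[1, metric_names()]),
    conf_low = unname(apply(boot, 2, stats::quantile, probs = alpha,
                            na.rm = TRUE, names = FALSE)),
    conf_high = unname(apply(boot, 2, stats::quantile, probs = 1 - alpha,
                             na.rm = TRUE, names = FALSE)))
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  class(out) <- c("ppc_metrics_ci", class(out))
  out
}

#' @export
autoplot.ppc_metrics_ci <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "estimate (95% CI)",
                  title = "Evaluation metrics with bootstrap intervals") +
    ggplot2::theme_minimal()
}
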