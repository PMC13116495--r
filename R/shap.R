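# flatten a ranger probability forest into the node arrays the C++ TreeSHAP
# kernel consumes; positive-class leaf probability is the node value
extract_forest <- function(rf) {
  n_trees <- rf$num.trees
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    ti <- ranger::treeInfo(rf, t)
    pred_col <- grep("^pred", names(ti), value = TRUE)
    pos_col <- pred_col[length(pred_col)]  # levels are c("0","1")
    trees[[t]] <- ti
    attr(trees[[t]], "pos_col") <- pos_col
  }
  sizes <- vapply(trees, nrow, integer(1))
  tree_start <- c(0L, cumsum(sizes))
  off <- tree_start[-length(tree_start)]
  left <- right <- feature <- integer(sum(sizes))
  threshold <- value <- numeric(sum(sizes))
  for (t in seq_len(n_trees)) {
    ti <- trees[[t]]
    idx <- seq_len(nrow(ti)) + off[t]
    term <- ti$terminal
    left[idx] <- ifelse(term, -1L, ti$leftChild + off[t])
    right[idx] <- ifelse(term, -1L, ti$rightChild + off[t])
    feature[idx] <- ifelse(term, -1L, ti$splitvarID)
    threshold[idx] <- ifelse(term, 0, ti$splitval)
    value[idx] <- ifelse(term, ti[[attr(ti, "pos_col")]], 0)
  }
  list(left = as.integer(left), right = as.integer(right),
       feature = as.integer(feature), threshold = threshold, value = value,
       tree_start = as.integer(tree_start))
}

#' Fit the preliminary random forest used for importance estimation
#'
#' A deliberately small forest (default 100 trees, depth 6, balanced class
#' weights) fitted on the index-encoded feature table; its only purpose is
#' to supply SHAP attributions from which input-scaling weights are
#' derived.
#'
#' @param x numeric/index-encoded feature data frame or matrix.
#' @param y binary labels (0/1).
#' @param num_trees,max_depth forest size (defaults 100 and 6).
#' @param seed integer RNG seed; fixed seed gives identical forests.
#' @return a `ppc_prelim_rf` object wrapping the fitted forest, its
#'   feature names and the training matrix (used as the background data
#'   for cover-weighted SHAP).
#' @export
fit_preliminary_rf <- function(x, y, num_trees = 100, max_depth = 6,
                               seed = 1) {
  x <- as.data.frame(x)
  if (!nrow(x)) stop("empty feature table", call. = FALSE)
  y <- as_binary(y, "y")
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit the preliminary forest",
         call. = FALSE)
  }
  tab <- table(factor(y, levels = c(0, 1)))
  cw <- as.numeric(sum(tab) / (2 * tab))
  df <- x
  df$.ppc_y <- factor(y, levels = c(0, 1))
  rf <- ranger::ranger(
    dependent.variable.name = ".ppc_y", data = df,
    num.trees = num_trees, max.depth = max_depth, probability = TRUE,
    class.weights = cw, seed = seed, num.threads = 1)
  structure(list(rf = rf, features = names(x), x_train = as.matrix(x)),
            class = "ppc_prelim_rf")
}

#' @export
predict.ppc_prelim_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[object$features]
  p <- predict(object$rf, newdata, num.threads = 1)$predictions
  unname(p[, ncol(p)])
}

#' Per-patient SHAP values for a preliminary forest
#'
#' Computes path-dependent TreeSHAP attributions: feature contributions
#' whose sum, plus the forest's cover-weighted base value, equals the
#' predicted positive-class probability for every patient.
#'
#' @param model a `ppc_prelim_rf` from [fit_preliminary_rf()].
#' @param data feature table to explain (defaults to the training table).
#' @return list with `phi` (patients x features matrix of SHAP values) and
#'   `base` (scalar expected prediction).
#' @export
shap_values <- function(model, data = NULL) {
  stopifnot(inherits(model, "ppc_prelim_rf"))
  X <- if (is.null(data)) model$x_train else as.matrix(as.data.frame(data)[model$features])
  if (!identical(colnames(X), model$features)) {
    stop("feature columns do not match the fitted model", call. = FALSE)
  }
  fr <- extract_forest(model$rf)
  cover <- forest_covers_cpp(fr$left, fr$right, fr$feature, fr$threshold,
                             fr$tree_start, model$x_train)
  res <- treeshap_forest_cpp(fr$left, fr$right, fr$feature, fr$threshold,
                             fr$value, cover, fr$tree_start,
                             length(model$features), X)
  phi <- res$phi
  colnames(phi) <- model$features
  list(phi = phi, base = res$base)
}

#' Mean absolute SHAP importance
#'
#' Global importance per feature: the mean over patients of the absolute
#' SHAP value. When a list of fold models (and matching tables) is given,
#' importance is additionally averaged across folds.
#'
#' @param model a `ppc_prelim_rf`, or a list of them (one per fold).
#' @param data feature table, or a list of tables matching `model`.
#' @return named numeric vector of raw importances (all `>= 0`).
#' @export
compute_mean_abs_shap <- function(model, data = NULL) {
  if (inherits(model, "ppc_prelim_rf")) {
    sv <- shap_values(model, data)
    return(colMeans(abs(sv$phi)))
  }
  stopifnot(is.list(model), length(model) >= 1L)
  if (is.null(data)) data <- vector("list", length(model))
  imps <- purrr::map2(model, data, ~ compute_mean_abs_shap(.x, .y))
  Reduce(`+`, imps) / length(imps)
}

#' Normalize raw importances to [0, 1]
#'
#' Division by the maximum, so the most important feature gets importance 1
#' and the weight bound `w <= 1 + lambda` is exact. An all-zero vector is
#' returned unchanged with a warning.
#'
#' @param raw named numeric vector of raw importances (all `>= 0`).
#' @return named numeric vector in `[0, 1]`.
#' @export
normalize_importance <- function(raw) {
  if (any(raw < 0)) stop("raw importances must be non-negative", call. = FALSE)
  m <- max(raw)
  if (m == 0) {
    warning("all raw importances are zero; returning zeros")
    return(raw)
  }
  raw / m
}

#' Importance-scaling input weights
#'
#' Converts normalized importances into per-feature input-scaling weights
#' \eqn{w_i = 1 + \lambda \cdot imp_i^{\gamma}}. Zero-importance features
#' keep weight 1 (the unweighted input); the most important feature gets
#' \eqn{1 + \lambda}. The tuned defaults are \eqn{\lambda = 0.27},
#' \eqn{\gamma = 0.82}.
#'
#' @param imp named numeric vector of normalized importances in `[0, 1]`.
#' @param lambda_ scaling strength, `>= 0`.
#' @param gamma_ nonlinearity exponent, `> 0`.
#' @param raw optional raw importances to carry along in the result.
#' @return tibble (class `ppc_importance`) with columns `feature`,
#'   `raw_importance`, `imp`, `w`; `lambda` and `gamma` stored as
#'   attributes.
#' @export
#' @examples
#' compute_feature_weights(c(a = 1, b = 0.5, c = 0))
compute_feature_weights <- function(imp, lambda_ = 0.27, gamma_ = 0.82,
                                    raw = NULL) {
  if (any(imp < 0 | imp > 1)) {
    stop("`imp` must lie in [0, 1]; did you forget normalize_importance()?",
         call. = FALSE)
  }
  if (lambda_ < 0) stop("`lambda_` must be >= 0", call. = FALSE)
  if (gamma_ <= 0) stop("`gamma_` must be > 0", call. = FALSE)
  w <- 1 + lambda_ * imp^gamma_
  out <- tibble::tibble(
    feature = if (is.null(names(imp))) paste0("f", seq_along(imp)) else names(imp),
    raw_importance = if (is.null(raw)) NA_real_ else unname(raw),
    imp = unname(imp),
    w = unname(w))
  attr(out, "lambda") <- lambda_
  attr(out, "gamma") <- gamma_
  class(out) <- c("ppc_importance", class(out))
  out
}

#' @export
tidy.ppc_importance <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
autoplot.ppc_importance <- function(object, top_n = 15, ...) {
  d <- dplyr::slice_max(tibble::as_tibble(object), .data$imp, n = top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, .data$imp),
                                  y = .data$imp)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized mean |SHAP|",
                  title = "Feature importance") +
    ggplot2::theme_minimal()
}

weights_for <- function(weights, features) {
  w <- weights$w[match(features, weights$feature)]
  if (anyNA(w)) {
    stop("weights do not cover feature(s): ",
         paste(features[is.na(w)], collapse = ", "), call. = FALSE)
  }
  w
}

#' Apply importance weights to an encoder input
#'
#' Scales the normalized numeric input columns elementwise by their weights
#' and records the per-feature weight each categorical/boolean embedding
#' vector is scaled by at lookup time. With `lambda = 0` all weights are 1
#' and the input is reproduced exactly.
#'
#' @param input an encoder input structure from [build_encoder_input()].
#' @param weights a `ppc_importance` tibble covering every input feature.
#' @return the input structure with `num` scaled and `cat_w` set.
#' @export
apply_weights <- function(input, weights) {
  stopifnot(inherits(input, "ppc_encoder_input"))
  w_num <- weights_for(weights, input$num_features)
  w_cat <- weights_for(weights, input$cat_features)
  input$num <- sweep(input$num, 2, w_num, `*`)
  input$num_w <- w_num
  input$cat_w <- w_cat
  input
}
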