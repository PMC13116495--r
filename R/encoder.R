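#' Encoder architecture configuration
#'
#' Two fully connected hidden layers (tuned sizes 256 and 64) with ReLU
#' activations and dropout; categorical and boolean features enter through
#' learned embedding vectors, numeric features as (weighted) z-scores. The
#' penultimate (hidden2) activations are the latent representation handed
#' to the forest head.
#'
#' @param hidden1,hidden2 hidden-layer widths (defaults 256, 64).
#' @param dropout dropout fraction in `[0, 1)` (default 0.43).
#' @param embedding_dim embedding width per categorical/boolean feature
#'   (default 8).
#' @param seed integer seed for weight initialization.
#' @return a `ppc_encoder_config` list.
#' @export
encoder_config <- function(hidden1 = 256, hidden2 = 64, dropout = 0.43,
                           embedding_dim = 8, seed = 1) {
  stopifnot(hidden1 >= 1, hidden2 >= 1, embedding_dim >= 1)
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  }
  structure(list(hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 dropout = dropout, embedding_dim = as.integer(embedding_dim),
                 seed = as.integer(seed)),
            class = "ppc_encoder_config")
}

#' Encoder training configuration
#'
#' Adam optimization with a linear learning-rate warm-up (from a tenth of
#' the configured rate up to it over `warmup_epochs`), early stopping on
#' validation AUROC with best-weight restoration, and the imbalance-aware
#' options: a positive-class loss weight (`"auto"` sets it to the
#' negative:positive count ratio), an inverse-frequency weighted
#' with-replacement batch sampler, and a choice between weighted
#' cross-entropy and focal loss.
#'
#' @param batch_size minibatch size (default 256).
#' @param learning_rate peak Adam learning rate (default 2.16e-3).
#' @param max_epochs maximum training epochs (default 50).
#' @param warmup_epochs warm-up length (default 5; must be below
#'   `max_epochs`).
#' @param early_stopping_patience epochs without validation-AUROC
#'   improvement before stopping (default 10).
#' @param pos_weight positive-class loss weight, a positive number or
#'   `"auto"`.
#' @param loss_kind `"weighted_bce"` or `"focal"`.
#' @param focal_alpha,focal_gamma focal-loss parameters (defaults 0.25, 2).
#' @param sampler `"weighted"` (inverse class frequency, with replacement)
#'   or `"plain"`.
#' @param seed integer seed for sampling, dropout and initialization order.
#' @return a `ppc_training_config` list.
#' @export
training_config <- function(batch_size = 256, learning_rate = 2.16e-3,
                            max_epochs = 50, warmup_epochs = 5,
                            early_stopping_patience = 10,
                            pos_weight = "auto",
                            loss_kind = c("weighted_bce", "focal"),
                            focal_alpha = 0.25, focal_gamma = 2,
                            sampler = c("weighted", "plain"), seed = 1) {
  loss_kind <- match.arg(loss_kind)
  sampler <- match.arg(sampler)
  if (warmup_epochs >= max_epochs) {
    stop("`warmup_epochs` must be below `max_epochs`", call. = FALSE)
  }
  if (is.numeric(pos_weight) && pos_weight <= 0) {
    stop("`pos_weight` must be positive", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 pos_weight = pos_weight, loss_kind = loss_kind,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 sampler = sampler, seed = as.integer(seed)),
            class = "ppc_training_config")
}

#' Positive-class loss weight from label counts
#'
#' @param labels binary labels with both classes present.
#' @return the ratio of negative to positive counts.
#' @export
#' @examples
#' compute_pos_weight(c(rep(0, 80), rep(1, 20)))  # 4
compute_pos_weight <- function(labels) {
  labels <- as_binary(labels, "labels")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L) stop("no positive labels", call. = FALSE)
  if (n_neg == 0L) stop("no negative labels", call. = FALSE)
  n_neg / n_pos
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Positive-weighted binary cross-entropy with logits
#'
#' Numerically stable logistic cross-entropy where the positive-class term
#' is multiplied by `pos_weight`; returns the mean over elements.
#'
#' @param logit real-valued scores.
#' @param label binary labels.
#' @param pos_weight positive-class multiplier (default 1).
#' @return nonnegative scalar loss.
#' @export
weighted_bce_loss <- function(logit, label, pos_weight = 1) {
  label <- as_binary(label, "label")
  # -[pw * y * log p + (1 - y) * log(1 - p)] in stable form
  mean(pos_weight * label * softplus(-logit) + (1 - label) * softplus(logit))
}

#' Focal loss
#'
#' Cross-entropy modulated by \eqn{(1 - p_t)^\gamma} to emphasize hard
#' examples; `alpha` multiplies the positive-class term (analogous to
#' `pos_weight`). With `gamma = 0` and `alpha = 1` this reduces exactly to
#' unweighted cross-entropy.
#'
#' @param logit real-valued scores.
#' @param label binary labels.
#' @param alpha positive-class weight (default 0.25).
#' @param gamma focusing exponent, `>= 0` (default 2).
#' @return nonnegative scalar loss (mean over elements).
#' @export
focal_loss <- function(logit, label, alpha = 0.25, gamma = 2) {
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  label <- as_binary(label, "label")
  log_pt <- -ifelse(label == 1, softplus(-logit), softplus(logit))
  pt <- exp(log_pt)
  alpha_t <- ifelse(label == 1, alpha, 1)
  mean(-alpha_t * (1 - pt)^gamma * log_pt)
}

# d(mean loss)/d(logit) for both loss kinds, scaled by 1/n
loss_grad <- function(logit, label, tr, pos_weight) {
  p <- stats::plogis(logit)
  n <- length(logit)
  if (tr$loss_kind == "weighted_bce") {
    (-pos_weight * label * (1 - p) + (1 - label) * p) / n
  } else {
    a <- tr$focal_alpha; g <- tr$focal_gamma
    pt <- ifelse(label == 1, p, 1 - p)
    log_pt <- -ifelse(label == 1, softplus(-logit), softplus(logit))
    alpha_t <- ifelse(label == 1, a, 1)
    dl_dpt <- -alpha_t * (-g * (1 - pt)^(pmax(g - 1, 0)) * log_pt +
                            (1 - pt)^g / pt)
    dpt_dz <- (2 * label - 1) * p * (1 - p)
    dl_dpt * dpt_dz / n
  }
}

#' Inverse-frequency sampler weights
#'
#' Per-sample weights proportional to the inverse of the class frequency,
#' so that with-replacement sampling yields an expected positive fraction
#' of one half per batch.
#'
#' @param labels binary labels with both classes present.
#' @return numeric vector of per-sample weights (sums to the sample count).
#' @export
make_sampler_weights <- function(labels) {
  labels <- as_binary(labels, "labels")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- length(labels)
  freq <- table(factor(labels, levels = c(0, 1))) / n
  w <- ifelse(labels == 1L, 1 / freq[["1"]], 1 / freq[["0"]])
  w / sum(w) * n
}

#' Build the encoder input structure from a raw cohort table
#'
#' Applies z-score normalization (training statistics) to the numeric
#' features and stable index coding to categorical and boolean features
#' (booleans are treated as 2-level categoricals so every feature has a
#' weightable embedding).
#'
#' @param data cohort data frame (raw feature values).
#' @param stats normalization statistics from [fit_normalization()].
#' @param schema schema tibble.
#' @return a `ppc_encoder_input` list: `num` (z-scored numeric matrix),
#'   `cat` (0-based index matrix), feature names, level counts, and unit
#'   weights.
#' @export
build_encoder_input <- function(data, stats, schema = ppc_schema()) {
  num_features <- schema_features(schema, "numeric")
  cat_features <- schema_features(schema, c("categorical", "boolean"))
  normed <- apply_normalization(data, stats)
  coded <- encode_categoricals(data, schema)
  num <- as.matrix(normed[num_features])
  cat_ <- as.matrix(coded[cat_features])
  storage.mode(cat_) <- "integer"
  n_levels <- vapply(cat_features, function(f) {
    length(schema$levels[[match(f, schema$name)]])
  }, integer(1))
  structure(list(num = num, cat = cat_, num_features = num_features,
                 cat_features = cat_features, n_levels = n_levels,
                 num_w = rep(1, length(num_features)),
                 cat_w = rep(1, length(cat_features))),
            class = "ppc_encoder_input")
}

init_encoder_params <- function(input, enc) {
  set.seed(enc$seed)
  e <- enc$embedding_dim
  p <- length(input$num_features)
  q <- length(input$cat_features)
  d_in <- p + q * e
  emb <- lapply(input$n_levels, function(L) {
    matrix(stats::rnorm(L * e, sd = 0.1), L, e)
  })
  names(emb) <- input$cat_features
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  list(emb = emb,
       W1 = he(d_in, enc$hidden1), b1 = numeric(enc$hidden1),
       W2 = he(enc$hidden1, enc$hidden2), b2 = numeric(enc$hidden2),
       w3 = matrix(stats::rnorm(enc$hidden2, sd = sqrt(2 / enc$hidden2)),
                   enc$hidden2, 1),
       b3 = 0)
}

# assemble the dense input block: weighted numerics then weighted embedding
# vectors per categorical feature
encoder_block <- function(params, input, rows) {
  q <- length(input$cat_features)
  e <- ncol(params$emb[[1]])
  num <- input$num[rows, , drop = FALSE]
  parts <- vector("list", q + 1L)
  parts[[1L]] <- num
  for (j in seq_len(q)) {
    E <- params$emb[[j]]
    parts[[j + 1L]] <- E[input$cat[rows, j] + 1L, , drop = FALSE] * input$cat_w[j]
  }
  do.call(cbind, parts)
}

relu <- function(x) (x > 0) * x

encoder_forward <- function(params, input, rows, dropout = 0, train = FALSE) {
  U <- encoder_block(params, input, rows)
  Z1 <- sweep(U %*% params$W1, 2, params$b1, `+`)
  H1 <- relu(Z1)
  M1 <- NULL
  if (train && dropout > 0) {
    M1 <- matrix(stats::runif(length(H1)) >= dropout, nrow(H1)) / (1 - dropout)
    H1 <- H1 * M1
  }
  Z2 <- sweep(H1 %*% params$W2, 2, params$b2, `+`)
  H2 <- relu(Z2)
  M2 <- NULL
  if (train && dropout > 0) {
    M2 <- matrix(stats::runif(length(H2)) >= dropout, nrow(H2)) / (1 - dropout)
    H2 <- H2 * M2
  }
  logit <- drop(H2 %*% params$w3) + params$b3
  list(U = U, Z1 = Z1, H1 = H1, M1 = M1, Z2 = Z2, H2 = H2, M2 = M2,
       logit = logit)
}

encoder_backward <- function(params, input, rows, fw, dlogit) {
  g <- list()
  dlogit <- matrix(dlogit, ncol = 1)
  g$w3 <- t(fw$H2) %*% dlogit
  g$b3 <- sum(dlogit)
  dH2 <- dlogit %*% t(params$w3)
  if (!is.null(fw$M2)) dH2 <- dH2 * fw$M2
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$W2 <- t(fw$H1) %*% dZ2
  g$b2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(params$W2)
  if (!is.null(fw$M1)) dH1 <- dH1 * fw$M1
  dZ1 <- dH1 * (fw$Z1 > 0)
  g$W1 <- t(fw$U) %*% dZ1
  g$b1 <- colSums(dZ1)
  dU <- dZ1 %*% t(params$W1)
  p <- length(input$num_features)
  e <- ncol(params$emb[[1]])
  g$emb <- vector("list", length(input$cat_features))
  names(g$emb) <- input$cat_features
  for (j in seq_along(input$cat_features)) {
    cols <- p + (j - 1L) * e + seq_len(e)
    dEj <- dU[, cols, drop = FALSE] * input$cat_w[j]
    codes <- input$cat[rows, j] + 1L
    G <- matrix(0, nrow(params$emb[[j]]), e)
    agg <- rowsum(dEj, group = codes)
    G[as.integer(rownames(agg)), ] <- agg
    g$emb[[j]] <- G
  }
  g
}

# flat iteration over the parameter list for the Adam update
param_walk <- function(params, fn) {
  for (nm in c("W1", "b1", "W2", "b2", "w3", "b3")) {
    params[[nm]] <- fn(nm, params[[nm]])
  }
  for (j in seq_along(params$emb)) {
    params$emb[[j]] <- fn(paste0("emb", j), params$emb[[j]])
  }
  params
}

#' Train the tabular encoder
#'
#' Minibatch Adam with a linear learning-rate warm-up, the configured
#' imbalance handling (positive-class loss weight and/or weighted sampler),
#' and early stopping on validation AUROC with restoration of the
#' best-epoch weights. Fully reproducible under the training seed.
#'
#' @param input training encoder input (weighted, from [apply_weights()] or
#'   raw from [build_encoder_input()]).
#' @param labels training labels.
#' @param val_input,val_labels validation split used for early stopping.
#' @param enc an [encoder_config()].
#' @param tr a [training_config()].
#' @return a `ppc_encoder_fit` list: `params` (best-epoch weights),
#'   `history` tibble (`epoch`, `lr`, `loss`, `val_auroc`), configs and the
#'   resolved `pos_weight`.
#' @export
train_encoder <- function(input, labels, val_input, val_labels,
                          enc = encoder_config(), tr = training_config()) {
  labels <- as_binary(labels, "labels")
  val_labels <- as_binary(val_labels, "val_labels")
  params <- init_encoder_params(input, enc)
  set.seed(tr$seed)
  n <- nrow(input$num)

  pos_weight <- if (identical(tr$pos_weight, "auto")) {
    compute_pos_weight(labels)
  } else tr$pos_weight
  samp_w <- if (tr$sampler == "weighted") make_sampler_weights(labels) else NULL

  adam_m <- adam_v <- list()
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0
  history <- vector("list", tr$max_epochs)
  best_auc <- -Inf; best_params <- params; best_epoch <- 0L; wait <- 0L

  for (epoch in seq_len(tr$max_epochs)) {
    lr <- if (epoch <= tr$warmup_epochs && tr$warmup_epochs > 1) {
      tr$learning_rate * (0.1 + 0.9 * (epoch - 1) / (tr$warmup_epochs - 1))
    } else tr$learning_rate
    idx <- if (is.null(samp_w)) {
      sample.int(n)
    } else {
      sample.int(n, n, replace = TRUE, prob = samp_w)
    }
    batches <- split(idx, ceiling(seq_along(idx) / tr$batch_size))
    ep_loss <- 0
    for (b in batches) {
      fw <- encoder_forward(params, input, b, enc$dropout, train = TRUE)
      y <- labels[b]
      l <- if (tr$loss_kind == "weighted_bce") {
        weighted_bce_loss(fw$logit, y, pos_weight)
      } else {
        focal_loss(fw$logit, y, tr$focal_alpha, tr$focal_gamma)
      }
      if (!is.finite(l)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      ep_loss <- ep_loss + l * length(b)
      dlogit <- loss_grad(fw$logit, y, tr, pos_weight)
      g <- encoder_backward(params, input, b, fw, dlogit)
      gflat <- c(g[c("W1", "b1", "W2", "b2", "w3", "b3")],
                 stats::setNames(g$emb, paste0("emb", seq_along(g$emb))))
      step <- step + 1
      params <- param_walk(params, function(nm, val) {
        gr <- gflat[[nm]]
        if (is.null(adam_m[[nm]])) {
          adam_m[[nm]] <<- gr * 0
          adam_v[[nm]] <<- gr * 0
        }
        adam_m[[nm]] <<- beta1 * adam_m[[nm]] + (1 - beta1) * gr
        adam_v[[nm]] <<- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        val - lr * mhat / (sqrt(vhat) + eps)
      })
    }
    val_logit <- encoder_forward(params, val_input,
                                 seq_len(nrow(val_input$num)))$logit
    val_auc <- roc_auc_value(val_labels, val_logit)
    history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                       loss = ep_loss / n,
                                       val_auroc = val_auc)
    if (is.finite(val_auc) && val_auc > best_auc) {
      best_auc <- val_auc; best_params <- params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tr$early_stopping_patience) break
    }
  }

  structure(list(params = best_params, enc = enc, tr = tr,
                 pos_weight = pos_weight, best_epoch = best_epoch,
                 best_val_auroc = best_auc,
                 history = dplyr::bind_rows(history)),
            class = "ppc_encoder_fit")
}

#' Extract latent representations
#'
#' Deterministic inference pass (dropout disabled) returning the
#' post-activation values of the second hidden layer, one row per patient.
#'
#' @param fit a `ppc_encoder_fit` from [train_encoder()].
#' @param input an encoder input (weighted with the same weights used in
#'   training).
#' @return numeric matrix, `n x hidden2`.
#' @export
extract_latents <- function(fit, input) {
  stopifnot(inherits(fit, "ppc_encoder_fit"))
  encoder_forward(fit$params, input, seq_len(nrow(input$num)))$H2
}
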