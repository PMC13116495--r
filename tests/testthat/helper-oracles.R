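# Independent oracle implementations used to cross-check the package.
# These are written from the definitions, never by calling the code paths
# they verify.

# direct-counting metric oracle; ROC-AUC via pairwise Mann-Whitney
# comparison, PR-AUC via an explicit threshold sweep
oracle_metrics <- function(labels, preds, probs) {
  tp <- sum(labels == 1 & preds == 1)
  fp <- sum(labels == 0 & preds == 1)
  fn <- sum(labels == 1 & preds == 0)
  tn <- sum(labels == 0 & preds == 0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(labels)
  f1p <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1n <- if (2 * tn + fn + fp == 0) 0 else 2 * tn / (2 * tn + fn + fp)
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  roc <- mean(cmp)
  thr <- sort(unique(probs), decreasing = TRUE)
  pr_pts <- t(vapply(thr, function(t) {
    p <- as.integer(probs >= t)
    c(prec = sum(labels == 1 & p == 1) / max(sum(p == 1), 1),
      rec = sum(labels == 1 & p == 1) / sum(labels == 1))
  }, c(prec = 0, rec = 0)))
  pr <- sum(diff(c(0, pr_pts[, "rec"])) * pr_pts[, "prec"])
  c(precision = prec, recall = rec, accuracy = acc,
    f1_macro = (f1p + f1n) / 2, roc_auc = roc, pr_auc = pr,
    specificity = spec)
}

# exhaustive threshold search: every midpoint between sorted unique
# probabilities plus 0.5, scored by positive-class F1, ties to the larger
# threshold
oracle_best_threshold <- function(probs, labels) {
  u <- sort(unique(probs))
  cand <- sort(unique(c((u[-1] + u[-length(u)]) / 2, 0.5)))
  f1 <- vapply(cand, function(t) {
    pred <- as.integer(probs > t)
    tp <- sum(labels == 1 & pred == 1)
    fp <- sum(labels == 0 & pred == 1)
    fn <- sum(labels == 1 & pred == 0)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(threshold = cand[max(which(f1 == max(f1)))], f1 = max(f1))
}

# path-dependent expectation of a single tree for a feature subset S
# (1-based feature ids): follow x on S, cover-weighted average elsewhere
oracle_tree_expect <- function(fr, cover, t, x, S) {
  walk <- function(node) {
    if (fr$left[node + 1] < 0) return(fr$value[node + 1])
    f <- fr$feature[node + 1] + 1
    if (f %in% S) {
      if (x[f] <= fr$threshold[node + 1]) walk(fr$left[node + 1])
      else walk(fr$right[node + 1])
    } else {
      cl <- cover[fr$left[node + 1] + 1]
      cr <- cover[fr$right[node + 1] + 1]
      (cl * walk(fr$left[node + 1]) + cr * walk(fr$right[node + 1])) /
        (cl + cr)
    }
  }
  walk(fr$tree_start[t])
}

# brute-force Shapley values by subset enumeration (small d only)
oracle_shapley <- function(fr, cover, x, d_feat) {
  n_trees <- length(fr$tree_start) - 1
  phi <- numeric(d_feat)
  for (t in seq_len(n_trees)) {
    for (i in seq_len(d_feat)) {
      rest <- setdiff(seq_len(d_feat), i)
      for (k in 0:length(rest)) {
        combs <- if (k == 0) list(integer(0)) else
          utils::combn(rest, k, simplify = FALSE)
        wgt <- factorial(k) * factorial(d_feat - k - 1) / factorial(d_feat)
        for (S in combs) {
          phi[i] <- phi[i] + wgt *
            (oracle_tree_expect(fr, cover, t, x, c(S, i)) -
               oracle_tree_expect(fr, cover, t, x, S))
        }
      }
    }
  }
  phi / n_trees
}

# a complete one-row record with every vital mid-range; override as needed
midrange_record <- function(...) {
  rec <- tibble::tibble(
    Age = 55, Gender = "F", Surgical_code_site = "gallbladder",
    Surgical_code_approach = "laparoscopic", Diagnostic_code = "benign_gi",
    Anesthesia_time = 100, Is_emergency = "elective", Stature = 160,
    Weight = 60, BMI = 23.4, Is_smoke = "never", Is_drinker = "no",
    Is_activity_free = "free", L_tube = "no", Hb_min = 12.5,
    SBP_max = 120, SBP_min = 100, DBP_max = 80, DBP_min = 65,
    BT_max = 37.0, BT_min = 36.4, RR_max = 16, RR_min = 13,
    PR_max = 85, PR_min = 70, Min_SpO2 = 98,
    Has_medical_history = "none", NRS_avg = 2,
    Systemic_infection_symptoms = FALSE,
    Bronchial_secretion_symptoms = FALSE, Respiratory_symptoms = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec <- ppcwatch:::derive_bins(rec)
  derive_judge_flags(rec)
}

# small configs that keep pipeline fits fast in unit tests
tiny_encoder <- function(seed = 1) {
  encoder_config(hidden1 = 32, hidden2 = 16, dropout = 0.2,
                 embedding_dim = 4, seed = seed)
}
tiny_training <- function(...) {
  training_config(batch_size = 64, max_epochs = 12, warmup_epochs = 3,
                  early_stopping_patience = 4, ...)
}
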