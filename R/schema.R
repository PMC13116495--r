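#' Feature schema for the postoperative cohort
#'
#' Returns the 41-feature schema used throughout the package: patient
#' characteristics, surgery/anesthesia descriptors, postoperative vital-sign
#' summaries (window minima/maxima), abnormality ("judge") flags, and
#' nursing-note-derived symptom booleans, plus the configurable normal
#' ranges the flags are derived from.
#'
#' Each row describes one feature. `kind` is one of `"numeric"`,
#' `"categorical"`, `"boolean"`. For numeric vitals, `normal_lo`/`normal_hi`
#' give the normal range used by [derive_judge_flags()] (`hi_exclusive`
#' marks a right-open range, e.g. a pain score is abnormal at or above the
#' upper cut), and `hard_lo`/`hard_hi` give physiologic hard bounds that any
#' valid record must satisfy. `judge` names the flag column a vital feeds,
#' if any. `levels` holds the ordered level set for categoricals and
#' booleans.
#'
#' Default normal ranges (all overridable via `normal_ranges`): SBP 90--140
#' mmHg, DBP 60--90 mmHg, body temperature 36.0--38.0 C, respiratory rate
#' 12--20 /min (inclusive), pulse rate 60--100 /min, SpO2 abnormal below
#' 95%, pain (NRS) abnormal at 4 or above.
#'
#' @param normal_ranges optional named list overriding normal ranges, each
#'   element `c(lo, hi)`, named by vital stem (`"SBP"`, `"DBP"`, `"BT"`,
#'   `"RR"`, `"PR"`, `"SpO2"`, `"NRS"`).
#' @return a tibble with one row per feature.
#' @export
#' @examples
#' ppc_schema()
ppc_schema <- function(normal_ranges = NULL) {
  rng <- list(
    SBP  = c(90, 140),
    DBP  = c(60, 90),
    BT   = c(36.0, 38.0),
    RR   = c(12, 20),
    PR   = c(60, 100),
    SpO2 = c(95, Inf),
    NRS  = c(-Inf, 4)
  )
  if (!is.null(normal_ranges)) {
    stopifnot(is.list(normal_ranges))
    bad <- setdiff(names(normal_ranges), names(rng))
    if (length(bad)) {
      stop("unknown vital stem in `normal_ranges`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(normal_ranges)) rng[[nm]] <- as.numeric(normal_ranges[[nm]])
  }

  num <- function(name, units, hard_lo, hard_hi, stem = NA_character_) {
    lo <- hi <- NA_real_; hx <- FALSE; judge <- NA_character_
    if (!is.na(stem)) {
      lo <- rng[[stem]][1]; hi <- rng[[stem]][2]
      hx <- identical(stem, "NRS")
      judge <- if (stem == "SpO2") "SpO2_judge" else paste0(stem, "_judge")
    }
    tibble::tibble(
      name = name, kind = "numeric", units = units,
      levels = list(NULL),
      normal_lo = lo, normal_hi = hi, hi_exclusive = hx,
      hard_lo = hard_lo, hard_hi = hard_hi, judge = judge
    )
  }
  cat_ <- function(name, levels) {
    tibble::tibble(
      name = name, kind = "categorical", units = NA_character_,
      levels = list(levels),
      normal_lo = NA_real_, normal_hi = NA_real_, hi_exclusive = FALSE,
      hard_lo = NA_real_, hard_hi = NA_real_, judge = NA_character_
    )
  }
  bool <- function(name) {
    tibble::tibble(
      name = name, kind = "boolean", units = NA_character_,
      levels = list(c("FALSE", "TRUE")),
      normal_lo = NA_real_, normal_hi = NA_real_, hi_exclusive = FALSE,
      hard_lo = NA_real_, hard_hi = NA_real_, judge = NA_character_
    )
  }

  dplyr::bind_rows(
    num("Age", "years", 19, 110),
    cat_("Age_1", c("19-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")),
    cat_("Gender", c("F", "M")),
    cat_("Surgical_code_site",
         c("gallbladder", "appendix", "colorectal", "stomach", "liver",
           "pancreas", "other")),
    cat_("Surgical_code_approach", c("laparoscopic", "open", "robotic")),
    cat_("Diagnostic_code",
         c("benign_gi", "gi_malignancy", "hepatobiliary_pancreatic_malignancy",
           "inflammatory", "other")),
    num("Anesthesia_time", "minutes", 15, 900),
    cat_("Anesthesia_time_1", c("<1h", "1-2h", "2-3h", "3-4h", ">4h")),
    cat_("Is_emergency", c("elective", "emergency")),
    num("Stature", "cm", 120, 210),
    num("Weight", "kg", 30, 200),
    num("BMI", "kg/m2", 12, 60),
    cat_("BMI_1", c("underweight", "normal", "overweight", "obese")),
    cat_("Is_smoke", c("never", "former", "current")),
    cat_("Is_drinker", c("no", "yes")),
    cat_("Is_activity_free", c("free", "limited")),
    cat_("L_tube", c("no", "yes")),
    num("Hb_min", "g/dL", 3, 22),
    num("SBP_max", "mmHg", 50, 260, "SBP"),
    num("SBP_min", "mmHg", 40, 240, "SBP"),
    num("DBP_max", "mmHg", 25, 160, "DBP"),
    num("DBP_min", "mmHg", 20, 150, "DBP"),
    num("BT_max", "C", 33, 43, "BT"),
    num("BT_min", "C", 32, 42, "BT"),
    num("RR_max", "/min", 5, 60, "RR"),
    num("RR_min", "/min", 4, 50, "RR"),
    num("PR_max", "/min", 25, 230, "PR"),
    num("PR_min", "/min", 20, 200, "PR"),
    num("Min_SpO2", "%", 40, 100, "SpO2"),
    bool("SBP_judge"),
    bool("DBP_judge"),
    bool("BT_judge"),
    bool("RR_judge"),
    bool("PR_judge"),
    bool("SpO2_judge"),
    bool("NRS_judge"),
    cat_("Has_medical_history", c("none", "single", "multiple")),
    num("NRS_avg", "score", 0, 10, "NRS"),
    bool("Systemic_infection_symptoms"),
    bool("Bronchial_secretion_symptoms"),
    bool("Respiratory_symptoms")
  )
}

#' Names of the feature columns in a cohort table
#'
#' @param schema a schema tibble from [ppc_schema()].
#' @param kind optional filter: `"numeric"`, `"categorical"` or `"boolean"`.
#' @return character vector of feature names.
#' @export
schema_features <- function(schema = ppc_schema(), kind = NULL) {
  if (!is.null(kind)) schema <- schema[schema$kind %in% kind, ]
  schema$name
}

# vital-summary columns that feed a given judge flag
judge_sources <- function(schema) {
  src <- schema[!is.na(schema$judge), c("name", "judge")]
  split(src$name, src$judge)
}

# abnormality test for one vital column against its schema row; returns
# logical vector, NA never produced (validated upstream)
is_abnormal_value <- function(x, row) {
  lo <- row$normal_lo
  hi <- row$normal_hi
  out <- x < lo | x > hi
  if (isTRUE(row$hi_exclusive)) out <- out | x >= hi
  out
}

#' Derive abnormality ("judge") flags from vital-sign summaries
#'
#' Recomputes the seven boolean abnormality flags from the window
#' vital-sign summaries: a flag is `TRUE` iff any of its source summaries
#' falls outside the configured normal range. SpO2 uses a one-sided rule
#' (abnormal iff below the lower threshold, default 95%), and the pain
#' score is abnormal at or above its upper cut (default 4).
#'
#' @param data a data frame containing the numeric vital-summary columns.
#' @param schema schema tibble from [ppc_schema()] (carries the ranges).
#' @return `data` with the seven `*_judge` columns set (added or replaced),
#'   as a tibble.
#' @export
#' @examples
#' rec <- tibble::tibble(SBP_max = 151, SBP_min = 113, DBP_max = 85,
#'   DBP_min = 65, BT_max = 37.1, BT_min = 36.4, RR_max = 20, RR_min = 14,
#'   PR_max = 88, PR_min = 72, Min_SpO2 = 95, NRS_avg = 2.125)
#' derive_judge_flags(rec)[, c("SBP_judge", "BT_judge", "SpO2_judge")]
derive_judge_flags <- function(data, schema = ppc_schema()) {
  data <- tibble::as_tibble(data)
  srcs <- judge_sources(schema)
  for (flag in names(srcs)) {
    cols <- intersect(srcs[[flag]], names(data))
    if (!length(cols)) next  # flag underivable from a partial record
    hit <- rep(FALSE, nrow(data))
    for (cl in cols) {
      row <- schema[schema$name == cl, ]
      x <- data[[cl]]
      if (any(x < row$hard_lo | x > row$hard_hi, na.rm = TRUE)) {
        stop("`", cl, "` outside physiologic hard bounds [", row$hard_lo,
             ", ", row$hard_hi, "]", call. = FALSE)
      }
      hit <- hit | is_abnormal_value(x, row)
    }
    data[[flag]] <- hit
  }
  data
}

# derived categorical bins are regenerated from the numeric sources, never
# trusted from input
derive_bins <- function(data) {
  data$Age_1 <- cut(data$Age, c(19, 30, 40, 50, 60, 70, 80, Inf),
                    labels = c("19-29", "30-39", "40-49", "50-59", "60-69",
                               "70-79", "80+"),
                    right = FALSE, include.lowest = TRUE)
  data$Age_1 <- as.character(data$Age_1)
  data$BMI_1 <- cut(data$BMI, c(-Inf, 18.5, 25, 30, Inf),
                    labels = c("underweight", "normal", "overweight", "obese"),
                    right = FALSE)
  data$BMI_1 <- as.character(data$BMI_1)
  data$Anesthesia_time_1 <- cut(data$Anesthesia_time,
                                c(-Inf, 60, 120, 180, 240, Inf),
                                labels = c("<1h", "1-2h", "2-3h", "3-4h", ">4h"),
                                right = FALSE)
  data$Anesthesia_time_1 <- as.character(data$Anesthesia_time_1)
  data
}

#' Fit z-score normalization statistics on training data
#'
#' Per-feature mean and standard deviation are estimated on the training
#' split only; test data must be transformed with the training statistics.
#'
#' @param train training cohort (data frame).
#' @param schema schema tibble.
#' @return tibble with columns `feature`, `mean`, `sd` (class
#'   `ppc_normalization`).
#' @export
fit_normalization <- function(train, schema = ppc_schema()) {
  if (!nrow(train)) stop("training data is empty", call. = FALSE)
  feats <- schema_features(schema, "numeric")
  feats <- intersect(feats, names(train))
  mu <- vapply(train[feats], mean, numeric(1))
  sd_ <- vapply(train[feats], stats::sd, numeric(1))
  zero <- feats[!is.finite(sd_) | sd_ <= 0]
  if (length(zero)) {
    stop("zero-variance numeric feature(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(feature = feats, mean = unname(mu), sd = unname(sd_))
  class(out) <- c("ppc_normalization", class(out))
  out
}

#' Apply normalization statistics
#'
#' @param data data frame to transform.
#' @param stats a `ppc_normalization` tibble from [fit_normalization()].
#' @return `data` with normalized numeric columns, as a tibble.
#' @export
apply_normalization <- function(data, stats) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    if (f %in% names(data)) data[[f]] <- (data[[f]] - stats$mean[i]) / stats$sd[i]
  }
  data
}

#' Encode categorical and boolean features as stable level indices
#'
#' Maps each categorical value to its 0-based index in the schema's ordered
#' level set and booleans to 0/1. The mapping is invertible via
#' [decode_categoricals()]. A level absent from the schema is an error;
#' there is no silent "other" bucket.
#'
#' @param data cohort data frame.
#' @param schema schema tibble.
#' @return tibble with categorical/boolean columns replaced by integer codes.
#' @export
encode_categoricals <- function(data, schema = ppc_schema()) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(schema))) {
    f <- schema$name[i]
    if (!f %in% names(data)) next
    if (schema$kind[i] == "categorical") {
      lev <- schema$levels[[i]]
      x <- as.character(data[[f]])
      idx <- match(x, lev)
      if (anyNA(idx)) {
        bad <- unique(x[is.na(idx)])
        stop("`", f, "` contains level(s) absent from the schema: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      data[[f]] <- idx - 1L
    } else if (schema$kind[i] == "boolean") {
      x <- data[[f]]
      if (is.character(x)) x <- as.logical(x)
      if (!is.logical(x) && !all(x %in% c(0, 1))) {
        stop("`", f, "` is not boolean-coded", call. = FALSE)
      }
      data[[f]] <- as.integer(x)
    }
  }
  data
}

#' Invert [encode_categoricals()]
#'
#' @param data an index-coded table.
#' @param schema schema tibble.
#' @return tibble with original level labels and logical booleans restored.
#' @export
decode_categoricals <- function(data, schema = ppc_schema()) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(schema))) {
    f <- schema$name[i]
    if (!f %in% names(data)) next
    if (schema$kind[i] == "categorical") {
      data[[f]] <- schema$levels[[i]][data[[f]] + 1L]
    } else if (schema$kind[i] == "boolean") {
      data[[f]] <- as.logical(data[[f]])
    }
  }
  data
}

#' Validate a cohort table against the schema
#'
#' Produces a report of schema violations rather than raising: missing
#' columns, missing values (any missing value is a hard failure -- the
#' modeling pipeline assumes complete data), values outside physiologic
#' hard bounds, categorical levels outside the level set, and judge flags
#' inconsistent with the vitals they summarize.
#'
#' @param data cohort data frame.
#' @param schema schema tibble.
#' @return tibble with columns `check`, `column`, `row`, `detail`; zero
#'   rows means the table conforms.
#' @export
validate_schema <- function(data, schema = ppc_schema()) {
  data <- tibble::as_tibble(data)
  issues <- list()
  add <- function(check, column, row, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      check = check, column = column, row = as.integer(row), detail = detail)
  }

  missing_cols <- setdiff(schema$name, names(data))
  for (mc in missing_cols) add("missing_column", mc, NA, "column absent")

  for (i in seq_len(nrow(schema))) {
    f <- schema$name[i]
    if (!f %in% names(data)) next
    x <- data[[f]]
    na_rows <- which(is.na(x))
    for (r in na_rows) add("missing_value", f, r, "missing value (complete data required)")
    ok <- !is.na(x)
    if (schema$kind[i] == "numeric") {
      bad <- which(ok & (x < schema$hard_lo[i] | x > schema$hard_hi[i]))
      for (r in bad) {
        add("out_of_bounds", f, r,
            sprintf("%g outside [%g, %g]", x[r], schema$hard_lo[i], schema$hard_hi[i]))
      }
    } else if (schema$kind[i] == "categorical") {
      bad <- which(ok & !(as.character(x) %in% schema$levels[[i]]))
      for (r in bad) add("unknown_level", f, r, paste0("level `", as.character(x[r]), "`"))
    } else {
      xv <- if (is.character(x)) as.logical(x) else x
      bad <- which(ok & !(xv %in% c(TRUE, FALSE, 0, 1)))
      for (r in bad) add("not_boolean", f, r, "value not in {TRUE, FALSE}")
    }
  }

  # flag/vital consistency: only when all sources are present, in bounds and
  # complete
  if (!length(issues) || !any(vapply(issues, function(z) z$check[1], "") %in%
                              c("missing_value", "out_of_bounds", "missing_column"))) {
    srcs <- judge_sources(schema)
    for (flag in names(srcs)) {
      if (!flag %in% names(data)) next
      cols <- srcs[[flag]]
      if (!all(cols %in% names(data))) next
      expected <- rep(FALSE, nrow(data))
      for (cl in cols) {
        row <- schema[schema$name == cl, ]
        expected <- expected | is_abnormal_value(data[[cl]], row)
      }
      got <- data[[flag]]
      if (is.character(got)) got <- as.logical(got)
      got <- as.logical(got)
      bad <- which(got != expected)
      for (r in bad) {
        add("flag_inconsistent", flag, r,
            sprintf("flag %s but vitals imply %s", got[r], expected[r]))
      }
    }
  }

  if (!length(issues)) {
    return(tibble::tibble(check = character(), column = character(),
                          row = integer(), detail = character()))
  }
  dplyr::bind_rows(issues)
}
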