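#' The 12-action nursing surveillance ontology
#'
#' One row per surveillance action: id, canonical text, risk tier
#' (`"basic"` actions require no abnormal finding; `"elevated"` actions
#' must be justified by a finding or by high predicted risk), and the
#' admissible-evidence set -- the features whose abnormality can justify
#' the action. The mapping groups respiratory observations (actions 1-2),
#' secretions (3), general vital-sign monitoring (4-5), temperature and
#' infection (6-7), pain (8-9), mobilization (10, basic) and physician
#' escalation (11-12, any abnormal finding).
#'
#' @return tibble with columns `id`, `action`, `tier`, `evidence`
#'   (list-column of feature names).
#' @export
action_ontology <- function() {
  vitals <- c("SBP_max", "SBP_min", "DBP_max", "DBP_min", "BT_max", "BT_min",
              "RR_max", "RR_min", "PR_max", "PR_min", "Min_SpO2")
  resp <- c("RR_max", "RR_min", "Min_SpO2", "Respiratory_symptoms")
  temp <- c("BT_max", "BT_min", "Systemic_infection_symptoms")
  anything <- c(vitals, "NRS_avg", "Systemic_infection_symptoms",
                "Bronchial_secretion_symptoms", "Respiratory_symptoms")
  tibble::tibble(
    id = 1:12,
    action = c(
      "Monitor the respiratory rate and breathing pattern",
      "Monitor cough and breathing discomfort",
      "Monitor the characteristics of the sputum",
      "Monitor oxygen saturation (SpO2)",
      "Verify intervals for vital signs and SpO2 monitoring",
      "Monitor body temperature",
      "Monitor symptoms: heat sensation, chills, shivering, facial flushing",
      "Monitor the level and pattern of pain",
      "Encourage the patient to express their pain",
      "Explain the importance of early ambulation and provide encouragement",
      "Communicate with the doctor about changes in patient status",
      "Communicate with the doctor about the necessity of a follow-up chest X-ray"),
    tier = c(rep("elevated", 9), "basic", "elevated", "elevated"),
    evidence = list(resp, resp, "Bronchial_secretion_symptoms",
                    vitals, vitals, temp, temp, "NRS_avg", "NRS_avg",
                    character(), anything, anything))
}

check_ontology <- function(ontology, schema) {
  if (!identical(sort(ontology$id), 1:12)) {
    stop("ontology ids must be exactly 1..12", call. = FALSE)
  }
  feats <- unique(unlist(ontology$evidence))
  bad <- setdiff(feats, schema$name)
  if (length(bad)) {
    stop("ontology references unknown feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(ontology)
}

threshold_label <- function(row, value) {
  if (isTRUE(row$hi_exclusive) && value >= row$normal_hi) {
    paste0(">= ", row$normal_hi)
  } else if (value > row$normal_hi) {
    paste0("> ", row$normal_hi)
  } else {
    paste0("< ", row$normal_lo)
  }
}

#' Assess a patient record for abnormal findings
#'
#' One finding per vital-sign summary outside its normal range and per
#' symptom boolean that is `TRUE`; each finding carries the feature, the
#' observed value and the violated threshold.
#'
#' @param record a one-row cohort data frame (must pass schema validation
#'   for the columns it contains).
#' @param schema schema tibble.
#' @return tibble with columns `feature`, `value`, `threshold`, `units`.
#' @export
#' @examples
#' rec <- tibble::tibble(SBP_max = 151, BT_max = 37.1, RR_max = 20,
#'                       Min_SpO2 = 95, NRS_avg = 2.125)
#' assess_patient(rec)
assess_patient <- function(record, schema = ppc_schema()) {
  stopifnot(nrow(record) == 1L)
  findings <- list()
  ranged <- schema[!is.na(schema$normal_lo) & schema$kind == "numeric", ]
  for (i in seq_len(nrow(ranged))) {
    f <- ranged$name[i]
    if (!f %in% names(record)) next
    v <- record[[f]]
    if (is.na(v)) stop("missing value in `", f, "`", call. = FALSE)
    if (v < ranged$hard_lo[i] || v > ranged$hard_hi[i]) {
      stop("`", f, "` outside physiologic hard bounds", call. = FALSE)
    }
    if (is_abnormal_value(v, ranged[i, ])) {
      findings[[length(findings) + 1L]] <- tibble::tibble(
        feature = f, value = v,
        threshold = threshold_label(ranged[i, ], v),
        units = ranged$units[i])
    }
  }
  symptoms <- c("Systemic_infection_symptoms", "Bronchial_secretion_symptoms",
                "Respiratory_symptoms")
  for (f in intersect(symptoms, names(record))) {
    v <- record[[f]]
    if (is.character(v)) v <- as.logical(v)
    if (isTRUE(as.logical(v))) {
      findings[[length(findings) + 1L]] <- tibble::tibble(
        feature = f, value = 1, threshold = "present", units = NA_character_)
    }
  }
  if (!length(findings)) {
    return(tibble::tibble(feature = character(), value = numeric(),
                          threshold = character(), units = character()))
  }
  dplyr::bind_rows(findings)
}

render_evidence <- function(feature, value, threshold, units) {
  if (identical(threshold, "present")) {
    paste0(gsub("_", " ", feature), ": present")
  } else {
    paste0(feature, ": ", value,
           ifelse(is.na(units) | units %in% c("score"), "", paste0(" ", units)),
           " (threshold ", threshold, ")")
  }
}

action_rationales <- function() {
  c("1" = "supports close observation of respiratory rate and breathing pattern for early deterioration",
    "2" = "warrants watching for cough and breathing discomfort",
    "3" = "warrants assessment of sputum characteristics",
    "4" = "requires oxygen-saturation monitoring to detect hypoxemia early",
    "5" = "requires verifying and tightening vital-sign and SpO2 monitoring intervals",
    "6" = "requires body-temperature monitoring",
    "7" = "warrants watching for systemic infection signs such as chills and flushing",
    "8" = "requires monitoring of pain level and pattern",
    "9" = "supports encouraging the patient to express pain",
    "10" = "routine postoperative care: early ambulation reduces pulmonary complication risk",
    "11" = "should be communicated to the doctor as a change in patient status",
    "12" = "may warrant discussing a follow-up chest X-ray with the doctor")
}

risk_evidence_feature <- ".predicted_risk"

#' Map findings and predicted risk to surveillance recommendations
#'
#' For each abnormal finding, every action whose admissible-evidence set
#' contains the finding's feature is emitted as one
#' action-evidence-rationale record (duplicates by action and feature are
#' removed). High predicted risk additionally emits the monitoring
#' defaults (actions 4 and 5) justified by the risk itself when no finding
#' already justifies them; the basic-tier action (10) is emitted for every
#' patient. No other action is emitted without a justifying finding.
#'
#' @param findings tibble from [assess_patient()].
#' @param risk_label `"high"` or `"low"`.
#' @param ontology the action ontology (default [action_ontology()]).
#' @param patient_id optional identifier carried into the records.
#' @param schema schema tibble (for ontology checking).
#' @return tibble (class `ppc_recommendations`) with columns `patient_id`,
#'   `risk`, `action_id`, `action`, `evidence_feature`, `evidence_value`,
#'   `evidence`, `rationale`.
#' @export
recommend_actions <- function(findings, risk_label,
                              ontology = action_ontology(),
                              patient_id = NA_character_,
                              schema = ppc_schema()) {
  if (!risk_label %in% c("high", "low")) {
    stop("`risk_label` must be \"high\" or \"low\"", call. = FALSE)
  }
  check_ontology(ontology, schema)
  rat <- action_rationales()
  recs <- list()
  emit <- function(id, feature, value, evidence, why) {
    recs[[length(recs) + 1L]] <<- tibble::tibble(
      patient_id = patient_id, risk = risk_label, action_id = id,
      action = ontology$action[ontology$id == id],
      evidence_feature = feature, evidence_value = value,
      evidence = evidence, rationale = why)
  }
  for (i in seq_len(nrow(findings))) {
    f <- findings[i, ]
    ev <- render_evidence(f$feature, f$value, f$threshold, f$units)
    for (id in ontology$id) {
      if (f$feature %in% ontology$evidence[[match(id, ontology$id)]]) {
        emit(id, f$feature, f$value, ev,
             paste0(sub(" \\(threshold.*$", "", ev), " ", rat[[as.character(id)]], "."))
      }
    }
  }
  done <- if (length(recs)) unique(dplyr::bind_rows(recs)$action_id) else integer()
  if (risk_label == "high") {
    for (id in setdiff(c(4L, 5L), done)) {
      emit(id, risk_evidence_feature, NA_real_, "predicted PPC risk: high",
           paste0("The patient is predicted to be at high risk of pulmonary complications; this ",
                  rat[[as.character(id)]], "."))
    }
  }
  emit(10L, risk_evidence_feature, NA_real_,
       paste0("predicted PPC risk: ", risk_label),
       paste0("Early ambulation is ", rat[["10"]], "."))
  out <- dplyr::distinct(dplyr::bind_rows(recs),
                         .data$action_id, .data$evidence_feature,
                         .keep_all = TRUE)
  out <- dplyr::arrange(out, .data$action_id)
  class(out) <- c("ppc_recommendations", class(out))
  out
}

#' Validate one recommendation against the patient record
#'
#' Labels: `unnecessary_action` when the cited evidence value is within
#' its normal range (or the cited symptom absent); `evidence_mismatch`
#' when the value is abnormal but the feature is not in the action's
#' admissible-evidence set; `correct` otherwise. A record citing predicted
#' risk is correct iff the action's tier matches the risk label (basic
#' actions always; elevated monitoring defaults only under high risk).
#' Scores are 5 for correct, 1 otherwise.
#'
#' @param rec a one-row recommendation (as produced by
#'   [recommend_actions()], or any row with `action_id`,
#'   `evidence_feature`, `evidence_value`, `risk`).
#' @param ontology,schema the action ontology and feature schema.
#' @return tibble with `label` and `score`.
#' @export
validate_recommendation <- function(rec, ontology = action_ontology(),
                                    schema = ppc_schema()) {
  stopifnot(nrow(rec) == 1L)
  if (!rec$action_id %in% ontology$id) {
    stop("unknown action id ", rec$action_id, call. = FALSE)
  }
  feature <- rec$evidence_feature
  admissible <- ontology$evidence[[match(rec$action_id, ontology$id)]]
  tier <- ontology$tier[match(rec$action_id, ontology$id)]
  if (identical(feature, risk_evidence_feature)) {
    ok <- tier == "basic" || identical(rec$risk, "high")
    label <- if (ok) "correct" else "unnecessary_action"
  } else {
    srow <- schema[schema$name == feature, ]
    if (!nrow(srow)) stop("unknown evidence feature `", feature, "`",
                          call. = FALSE)
    abnormal <- if (srow$kind == "boolean") {
      isTRUE(as.logical(rec$evidence_value))
    } else {
      is_abnormal_value(rec$evidence_value, srow)
    }
    label <- if (!abnormal) {
      "unnecessary_action"
    } else if (!feature %in% admissible) {
      "evidence_mismatch"
    } else {
      "correct"
    }
  }
  tibble::tibble(label = label, score = ifelse(label == "correct", 5L, 1L))
}

#' Validate every row of a recommendation set
#'
#' @param recs recommendations tibble.
#' @param ontology,schema see [validate_recommendation()].
#' @return `recs` with `label` and `score` columns appended.
#' @export
validate_recommendations <- function(recs, ontology = action_ontology(),
                                     schema = ppc_schema()) {
  labs <- purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    validate_recommendation(recs[i, ], ontology, schema)
  })
  dplyr::bind_cols(tibble::as_tibble(recs), labs)
}

#' Per-patient score bin
#'
#' Averages the per-action scores (5 for correct, 1 otherwise) and rounds
#' half-up to the nearest integer bin in 1..5.
#'
#' @param scores integer vector of per-action scores.
#' @return integer bin in 1..5.
#' @export
#' @examples
#' score_patient(c(5, 5, 1))  # mean 11/3 -> bin 4
score_patient <- function(scores) {
  if (!length(scores)) stop("no scores to average", call. = FALSE)
  if (!all(scores %in% c(1L, 5L))) {
    stop("scores must be 5 (correct) or 1 (incorrect)", call. = FALSE)
  }
  bin <- floor(mean(scores) + 0.5)
  as.integer(min(max(bin, 1L), 5L))
}

#' Five-bin frequency table of patient scores
#'
#' @param bins integer vector of per-patient bins in 1..5.
#' @return one-row tibble with counts `score_5` .. `score_1` and `total`.
#' @export
summarize_scores <- function(bins) {
  if (length(bins) && !all(bins %in% 1:5)) {
    stop("bins must be integers in 1..5", call. = FALSE)
  }
  counts <- table(factor(bins, levels = 5:1))
  out <- tibble::as_tibble(as.list(stats::setNames(
    as.integer(counts), paste0("score_", 5:1))))
  out$total <- length(bins)
  out
}

#' Serialize recommendations to per-patient JSON documents
#'
#' Each document holds the patient id, the risk label and the list of
#' `{"action": [...], "evidence": "...", "rationale": "..."}` triples
#' (plus the structured fields needed for a lossless round trip via
#' [parse_recommendations()]). The document structure is described by the
#' JSON Schema shipped at
#' `system.file("extdata", "recommendation.schema.json", package = "ppcwatch")`.
#'
#' @param recs recommendations tibble.
#' @return named character vector, one JSON document per patient.
#' @export
serialize_recommendations <- function(recs) {
  recs <- tibble::as_tibble(recs)
  needed <- c("patient_id", "risk", "action_id", "action",
              "evidence_feature", "evidence_value", "evidence", "rationale")
  missing <- setdiff(needed, names(recs))
  if (length(missing)) {
    stop("recommendations lack field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  docs <- recs |>
    dplyr::group_by(.data$patient_id, .data$risk) |>
    dplyr::group_map(function(g, key) {
      list(patient_id = key$patient_id, risk = key$risk,
           recommendations = lapply(seq_len(nrow(g)), function(i) {
             list(action = list(g$action[i]), action_id = g$action_id[i],
                  evidence = g$evidence[i],
                  evidence_feature = g$evidence_feature[i],
                  evidence_value = g$evidence_value[i],
                  rationale = g$rationale[i])
           }))
    })
  out <- vapply(docs, function(d) {
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, character(1))
  names(out) <- vapply(docs, `[[`, character(1), "patient_id")
  out
}

#' Parse per-patient recommendation JSON back to a tibble
#'
#' @param docs character vector of JSON documents from
#'   [serialize_recommendations()].
#' @return recommendations tibble.
#' @export
parse_recommendations <- function(docs) {
  purrr::map_dfr(docs, function(txt) {
    d <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
    check_recommendation_doc(d)
    purrr::map_dfr(d$recommendations, function(r) {
      tibble::tibble(patient_id = d$patient_id, risk = d$risk,
                     action_id = as.integer(r$action_id),
                     action = r$action[[1]],
                     evidence_feature = r$evidence_feature,
                     evidence_value = if (is.null(r$evidence_value))
                       NA_real_ else as.numeric(r$evidence_value),
                     evidence = r$evidence, rationale = r$rationale)
    })
  })
}

check_recommendation_doc <- function(d) {
  top <- c("patient_id", "risk", "recommendations")
  missing <- setdiff(top, names(d))
  if (length(missing)) {
    stop("recommendation document lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!d$risk %in% c("high", "low")) {
    stop("recommendation document has invalid risk label", call. = FALSE)
  }
  for (r in d$recommendations) {
    miss <- setdiff(c("action", "evidence", "rationale"), names(r))
    if (length(miss)) {
      stop("recommendation triple lacks field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(d)
}

#' Build the language-model prompt for a patient
#'
#' Deterministic prompt: the role/format instruction, the patient status
#' as itemized bullets, and the JSON-format directive. The package's rule
#' engine does not use this; it exists so an external language model can
#' be slotted into the same pipeline and its outputs validated and scored
#' with the same tools.
#'
#' @param record one-row cohort data frame.
#' @param risk_label `"high"` or `"low"`.
#' @param schema schema tibble (for units).
#' @return a single character string.
#' @export
build_llm_prompt <- function(record, risk_label, schema = ppc_schema()) {
  stopifnot(nrow(record) == 1L, risk_label %in% c("high", "low"))
  header <- paste0(
    "You are a highly precise nursing surveillance support system. ",
    "This patient was at a ", risk_label,
    " risk of developing pulmonary complications. ",
    "Provide a list of nursing interventions for the patient below and ",
    "output the evidence and theoretical explanations in JSON format.")
  feats <- intersect(schema$name, names(record))
  bullets <- vapply(feats, function(f) {
    u <- schema$units[match(f, schema$name)]
    v <- record[[f]]
    paste0("- ", gsub("_", " ", f), ": ", as.character(v),
           ifelse(is.na(u) || u == "score", "", paste0(" ", u)))
  }, character(1))
  footer <- paste0(
    "Respond only with JSON using the structure ",
    '{"action": [...], "evidence": "...", "rationale": "..."}.')
  paste(c(header, "", bullets, "", footer), collapse = "\n")
}

#' Recommendations for every patient in a cohort
#'
#' Couples the fitted risk model with the rule engine: predicts each
#' patient's risk class at the model's calibrated threshold, assesses
#' abnormal findings, and emits validated recommendations.
#'
#' @param model a fitted `ppc_model`.
#' @param data cohort tibble.
#' @param ontology action ontology.
#' @return recommendations tibble with validation `label` and `score`
#'   columns.
#' @export
ppc_recommend <- function(model, data, ontology = action_ontology()) {
  preds <- predict(model, data)
  schema <- model$schema
  recs <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    findings <- assess_patient(data[i, ], schema)
    recommend_actions(findings,
                      risk_label = ifelse(preds$.pred_class[i] == 1L,
                                          "high", "low"),
                      ontology = ontology,
                      patient_id = as.character(data$patient_id[i]),
                      schema = schema)
  })
  validate_recommendations(recs, ontology, schema)
}
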