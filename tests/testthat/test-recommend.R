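table6_record <- function() {
  midrange_record(Hb_min = 11.7, SBP_max = 151, SBP_min = 113, DBP_max = 85,
                  DBP_min = 65, BT_max = 37.1, BT_min = 36.4, RR_max = 20,
                  RR_min = 14, PR_max = 85, PR_min = 70, Min_SpO2 = 95,
                  NRS_avg = 2.125,
                  Systemic_infection_symptoms = FALSE,
                  Bronchial_secretion_symptoms = FALSE,
                  Respiratory_symptoms = FALSE)
}

test_that("the ontology has exactly twelve valid actions", {
  ont <- action_ontology()
  expect_identical(ont$id, 1:12)
  expect_identical(ont$tier[ont$id == 10], "basic")
  expect_true(all(unlist(ont$evidence) %in% ppc_schema()$name))
  expect_match(ont$action[4], "oxygen saturation", ignore.case = TRUE)
  bad <- ont
  bad$id[1] <- 99L
  expect_error(ppcwatch:::check_ontology(bad, ppc_schema()), "1\\.\\.12")
})

test_that("assessment of the case-study patient flags only elevated SBP", {
  f <- assess_patient(table6_record())
  expect_identical(f$feature, "SBP_max")
  expect_identical(f$value, 151)
  expect_identical(f$threshold, "> 140")
})

test_that("low SpO2 is assessed against the one-sided threshold", {
  f <- assess_patient(midrange_record(Min_SpO2 = 90))
  expect_true("Min_SpO2" %in% f$feature)
  expect_identical(f$threshold[f$feature == "Min_SpO2"], "< 95")
})

test_that("an unremarkable record yields no findings", {
  expect_identical(nrow(assess_patient(midrange_record())), 0L)
})

test_that("the engine recommends vital-sign verification for the case study", {
  f <- assess_patient(table6_record())
  recs <- recommend_actions(f, "high", patient_id = "case1")
  expect_true(5L %in% recs$action_id)
  r5 <- recs[recs$action_id == 5L, ]
  expect_identical(r5$evidence_feature, "SBP_max")
  expect_match(r5$evidence, "151")
  # SBP does not justify the respiratory actions
  expect_false(1L %in% recs$action_id)
})

test_that("risk tiers drive the default actions", {
  none <- assess_patient(midrange_record())
  low <- recommend_actions(none, "low")
  expect_identical(low$action_id, 10L)
  high <- recommend_actions(none, "high")
  expect_setequal(high$action_id, c(4L, 5L, 10L))
  spo2 <- recommend_actions(assess_patient(midrange_record(Min_SpO2 = 90)),
                            "high")
  expect_true(4L %in% spo2$action_id)
  expect_identical(spo2$evidence_feature[spo2$action_id == 4L], "Min_SpO2")
  expect_error(recommend_actions(none, "medium"), "high")
})

test_that("the validator reproduces the three case-study labels", {
  mk <- function(id, feature, value) {
    tibble::tibble(patient_id = "case1", risk = "high", action_id = id,
                   action = action_ontology()$action[id],
                   evidence_feature = feature, evidence_value = value,
                   evidence = "", rationale = "")
  }
  expect_identical(validate_recommendation(mk(5L, "SBP_max", 151))$label,
                   "correct")
  expect_identical(validate_recommendation(mk(6L, "BT_max", 37.1))$label,
                   "unnecessary_action")
  expect_identical(validate_recommendation(mk(1L, "SBP_max", 151))$label,
                   "evidence_mismatch")
  expect_identical(validate_recommendation(mk(5L, "SBP_max", 151))$score, 5L)
  expect_identical(validate_recommendation(mk(6L, "BT_max", 37.1))$score, 1L)
  expect_error(validate_recommendation(mk(5L, "NoSuchVital", 1)), "unknown")
})

test_that("every engine-emitted recommendation validates as correct", {
  co <- generate_cohort(cohort_config(60, seed = 50))
  recs <- purrr::map_dfr(1:30, function(i) {
    recommend_actions(assess_patient(co[i, ]),
                      risk_label = ifelse(co$ppc[i] == 1, "high", "low"),
                      patient_id = co$patient_id[i])
  })
  checked <- validate_recommendations(recs)
  expect_true(all(checked$label == "correct"))
  expect_true(all(checked$score == 5L))
})

test_that("patient scores average half-up into five bins", {
  expect_identical(score_patient(c(5L, 5L, 5L)), 5L)
  expect_identical(score_patient(c(5L, 5L, 1L)), 4L)  # mean 11/3 -> 4
  expect_identical(score_patient(c(5L, 1L, 1L)), 2L)  # mean 7/3 -> 2
  expect_identical(score_patient(c(5L, 1L)), 3L)      # mean 3 -> 3
  expect_identical(score_patient(1L), 1L)
  expect_error(score_patient(integer(0)), "no scores")
  expect_error(score_patient(c(5L, 3L)), "5 .* or 1")
})

test_that("score summaries tally and conserve the patient count", {
  s <- summarize_scores(rep(5L, 100))
  expect_identical(s$score_5, 100L)
  expect_identical(s$total, 100L)
  set.seed(6)
  bins <- sample(1:5, 87, replace = TRUE)
  s2 <- summarize_scores(bins)
  expect_identical(s2$total, 87L)
  expect_identical(sum(s2$score_5, s2$score_4, s2$score_3, s2$score_2,
                       s2$score_1), 87L)
  tab <- table(factor(bins, levels = 5:1))
  expect_identical(s2$score_3, as.integer(tab[["3"]]))
})

test_that("serialization round-trips losslessly with the canonical keys", {
  co <- generate_cohort(cohort_config(40, seed = 51))
  recs <- purrr::map_dfr(1:20, function(i) {
    recommend_actions(assess_patient(co[i, ]),
                      risk_label = ifelse(co$ppc[i] == 1, "high", "low"),
                      patient_id = co$patient_id[i])
  })
  docs <- serialize_recommendations(recs)
  expect_identical(length(docs), length(unique(recs$patient_id)))
  parsed <- jsonlite::fromJSON(docs[[1]], simplifyVector = FALSE)
  expect_true(all(c("action", "evidence", "rationale") %in%
                    names(parsed$recommendations[[1]])))
  back <- parse_recommendations(docs)
  cols <- c("patient_id", "risk", "action_id", "action", "evidence_feature",
            "evidence", "rationale")
  expect_identical(dplyr::arrange(back[cols], .data$patient_id, .data$action_id),
                   dplyr::arrange(tibble::as_tibble(recs)[cols],
                                  .data$patient_id, .data$action_id))
})

test_that("malformed documents are rejected with the offending fields", {
  expect_error(parse_recommendations('{"risk": "high"}'), "patient_id")
  expect_error(parse_recommendations(
    '{"patient_id": "x", "risk": "high", "recommendations": [{"action": ["a"]}]}'),
    "evidence")
})

test_that("the prompt builder is deterministic and itemized", {
  rec <- midrange_record(Age = 82, Gender = "F",
                         Surgical_code_site = "gallbladder")
  p1 <- build_llm_prompt(rec, "high")
  expect_match(p1, "You are a highly precise nursing surveillance support system",
               fixed = TRUE)
  expect_match(p1, "- Age: 82 years", fixed = TRUE)
  expect_match(p1, "- Gender: F", fixed = TRUE)
  expect_match(p1, "JSON", fixed = TRUE)
  expect_identical(p1, build_llm_prompt(rec, "high"))
  expect_false(identical(p1, build_llm_prompt(rec, "low")))
})
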