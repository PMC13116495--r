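test_that("schema declares 41 uniquely named features with sane ranges", {
  schema <- ppc_schema()
  expect_identical(nrow(schema), 41L)
  expect_identical(anyDuplicated(schema$name), 0L)
  ranged <- schema[!is.na(schema$normal_lo), ]
  expect_true(all(ranged$normal_lo >= ranged$hard_lo - 1e-9 |
                    !is.finite(ranged$normal_lo)))
  expect_true(all(ranged$normal_hi <= ranged$hard_hi + 1e-9 |
                    !is.finite(ranged$normal_hi)))
  cats <- schema[schema$kind != "numeric", ]
  expect_true(all(lengths(cats$levels) >= 2))
})

test_that("judge flags follow the configured normal ranges", {
  rec <- midrange_record(SBP_max = 151, BT_max = 37.1, RR_max = 20,
                         Min_SpO2 = 95, NRS_avg = 2.125)
  expect_true(rec$SBP_judge)     # 151 outside [90, 140]
  expect_false(rec$BT_judge)     # 37.1 within [36, 38]
  expect_false(rec$RR_judge)     # 20 inclusive upper bound
  expect_false(rec$SpO2_judge)   # 95 not below the < 95 cut
  expect_false(rec$NRS_judge)    # 2.125 below the >= 4 cut

  low <- midrange_record(Min_SpO2 = 90, NRS_avg = 4)
  expect_true(low$SpO2_judge)
  expect_true(low$NRS_judge)
})

test_that("either summary of a vital pair can trip its flag", {
  expect_true(midrange_record(SBP_min = 85)$SBP_judge)
  expect_true(midrange_record(PR_min = 46)$PR_judge)
  expect_true(midrange_record(BT_min = 35.8)$BT_judge)
})

test_that("flag derivation is idempotent and matches a brute-force recheck", {
  co <- generate_cohort(cohort_config(300, seed = 21))
  once <- derive_judge_flags(co)
  twice <- derive_judge_flags(once)
  expect_identical(once, twice)
  schema <- ppc_schema()
  # brute force: per record, per flag, re-evaluate every source vital
  srcs <- ppcwatch:::judge_sources(schema)
  for (flag in names(srcs)) {
    manual <- vapply(seq_len(nrow(co)), function(i) {
      any(vapply(srcs[[flag]], function(cl) {
        row <- schema[schema$name == cl, ]
        v <- co[[cl]][i]
        v < row$normal_lo || v > row$normal_hi ||
          (row$hi_exclusive && v >= row$normal_hi)
      }, logical(1)))
    }, logical(1))
    expect_identical(once[[flag]], manual)
  }
})

test_that("vitals outside hard bounds are a data-quality error", {
  rec <- midrange_record()
  rec$SBP_max <- 400
  expect_error(derive_judge_flags(rec), "hard bounds")
})

test_that("normal ranges are configurable", {
  schema <- ppc_schema(normal_ranges = list(SBP = c(100, 130)))
  rec <- tibble::tibble(SBP_max = 135, SBP_min = 110)
  out <- derive_judge_flags(rec, schema)
  expect_true(out$SBP_judge)
  expect_error(ppc_schema(normal_ranges = list(XYZ = c(0, 1))), "unknown vital")
})

test_that("normalization is a train-only z-score with exact identities", {
  train <- tibble::tibble(Age = c(1, 2, 3))
  st <- fit_normalization(train, ppc_schema()[ppc_schema()$name == "Age", ])
  expect_identical(st$mean, 2)
  expect_identical(st$sd, sd(c(1, 2, 3)))
  z <- apply_normalization(train, st)
  expect_equal(sum(z$Age), 0, tolerance = 1e-12)
  expect_identical(apply_normalization(tibble::tibble(Age = 2), st)$Age, 0)

  co <- generate_cohort(cohort_config(200, seed = 2))
  st2 <- fit_normalization(co)
  z2 <- apply_normalization(co, st2)
  for (f in c("Age", "PR_max", "Min_SpO2")) {
    expect_lt(abs(mean(z2[[f]])), 1e-9)
    expect_lt(abs(sd(z2[[f]]) - 1), 1e-9)
  }
  # stats depend only on the training split, not on what they are applied to
  st3 <- fit_normalization(co)
  expect_identical(st2, st3)
})

test_that("zero-variance features are rejected by name", {
  co <- generate_cohort(cohort_config(50, seed = 2))
  co$Hb_min <- 12
  expect_error(fit_normalization(co), "Hb_min")
})

test_that("categorical encoding is stable, invertible, and strict", {
  co <- generate_cohort(cohort_config(150, seed = 4))
  enc <- encode_categoricals(co)
  expect_identical(sort(unique(enc$Gender)), c(0L, 1L))
  expect_identical(enc$Gender, as.integer(co$Gender == "M"))
  back <- decode_categoricals(enc)
  expect_identical(back[names(co)], co)
  bad <- co
  bad$Surgical_code_site[3] <- "knee"
  expect_error(encode_categoricals(bad), "absent from the schema")
})

test_that("validate_schema reports nothing on a conforming cohort", {
  co <- generate_cohort(cohort_config(80, seed = 6))
  expect_identical(nrow(validate_schema(co)), 0L)
})

test_that("validate_schema names missing cells and inconsistent flags", {
  co <- generate_cohort(cohort_config(40, seed = 6))
  co$Age[7] <- NA
  rep1 <- validate_schema(co)
  expect_true(any(rep1$check == "missing_value" & rep1$column == "Age" &
                    rep1$row == 7))

  co2 <- generate_cohort(cohort_config(40, seed = 6))
  co2$SBP_max[5] <- 180
  co2$SBP_judge[5] <- FALSE
  rep2 <- validate_schema(co2)
  expect_true(any(rep2$check == "flag_inconsistent" &
                    rep2$column == "SBP_judge" & rep2$row == 5))

  co3 <- generate_cohort(cohort_config(40, seed = 6))
  co3$Min_SpO2[2] <- 20
  rep3 <- validate_schema(co3)
  expect_true(any(rep3$check == "out_of_bounds" & rep3$column == "Min_SpO2"))
})
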