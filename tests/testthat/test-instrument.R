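test_that("age bins map to the published weights, edges inclusive", {
  cases <- rbind(
    c(50, 0), c(59, 0), c(60, 1), c(69, 1), c(70, 2), c(76, 2), c(79, 2),
    c(80, 3), c(89, 3), c(90, 4), c(104, 4)
  )
  expect_equal(age_risk_points(cases[, 1]), as.integer(cases[, 2]))
  # fractional ages floored to whole years
  expect_equal(age_risk_points(59.9), 0L)
  expect_error(age_risk_points(49), "50")
})

test_that("risk score reproduces hand-summed weight-table examples", {
  # female, age 92, all eight weighted factors: the 18-point maximum
  allmax <- risk_profile(92, "female", education_lt6 = TRUE, bmi_lt18 = TRUE,
                         stroke = TRUE, diabetes = TRUE, hypertension = TRUE,
                         hyperlipidemia = TRUE, head_trauma_loc = TRUE,
                         depression = TRUE)
  expect_equal(risk_score(allmax), 18L)
  # male, age 55, nothing else: minimum is the single sex point
  expect_equal(risk_score(risk_profile(55, "male")), 1L)
  # female 72 + education + diabetes + depression = 2+2+1+1+3
  expect_equal(risk_score(risk_profile(72, "female", education_lt6 = TRUE,
                                       diabetes = TRUE, depression = TRUE)),
               9L)
})

test_that("risk score is monotone in age and in every binary factor", {
  base <- list(age = 63, sex = "male")
  flags <- c("education_lt6", "bmi_lt18", "stroke", "diabetes",
             "hypertension", "hyperlipidemia", "head_trauma_loc",
             "depression")
  rs0 <- risk_score(do.call(risk_profile, base))
  for (f in flags) {
    args <- base; args[[f]] <- TRUE
    expect_gte(risk_score(do.call(risk_profile, args)), rs0)
  }
  ages <- c(50, 61, 72, 85, 95)
  rs_by_age <- vapply(ages, function(a) risk_score(risk_profile(a, "male")),
                      integer(1))
  expect_true(all(diff(rs_by_age) >= 0))
  # bounds over a grid of random profiles
  set.seed(11)
  for (i in 1:50) {
    args <- c(list(age = sample(50:99, 1),
                   sex = sample(c("male", "female"), 1)),
              stats::setNames(as.list(as.logical(rbinom(8, 1, 0.5))), flags))
    rs <- risk_score(do.call(risk_profile, args))
    expect_gte(rs, 1L); expect_lte(rs, 18L)
  }
})

test_that("high-risk triage applies exactly the three published criteria", {
  quiet <- risk_profile(72, "female", diabetes = TRUE)   # rs = 5
  expect_false(is_high_risk(quiet))
  # criterion 3 at its boundary: rs >= 8 triggers, 7 does not
  rs8 <- risk_profile(85, "female", stroke = TRUE, diabetes = TRUE,
                      hypertension = TRUE)               # 3+2+3 = 8
  expect_equal(risk_score(rs8), 8L)
  expect_true(is_high_risk(rs8))
  rs7 <- risk_profile(85, "female", stroke = TRUE, diabetes = TRUE)
  expect_equal(risk_score(rs7), 7L)
  expect_false(is_high_risk(rs7))
  # criterion 1: either complaint source suffices
  expect_true(is_high_risk(risk_profile(55, "male",
                                        memory_decline_informant = TRUE)))
  expect_true(is_high_risk(risk_profile(55, "male",
                                        memory_decline_subject = TRUE)))
  # criterion 2
  expect_true(is_high_risk(risk_profile(55, "male",
                                        needs_assistance_money_meds = TRUE)))
  # doctor-reported impairment alone does NOT trigger triage
  expect_false(is_high_risk(risk_profile(55, "male",
                                         memory_impairment_doctor = TRUE)))
})

test_that("fluency binning follows the published bins and is monotone", {
  expect_equal(fluency_points(c(0, 4, 5, 8, 9, 25)),
               c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_true(all(diff(fluency_points(0:30)) >= 0))
  expect_error(fluency_points(-1), "non-negative")
})

test_that("BHT-cog total sums the four items, bounded 0-16 and monotone", {
  expect_equal(bht_cog_score(cognitive_raw(4, 5, 12, 5)), 16L)
  expect_equal(bht_cog_score(cognitive_raw(0, 0, 0, 0)), 0L)
  expect_equal(bht_cog_score(cognitive_raw(3, 3, 7, 2)), 9L)
  # monotone in every raw item
  base <- c(2, 3, 6, 2)
  s0 <- bht_cog_score(do.call(cognitive_raw, as.list(base)))
  for (i in 1:4) {
    up <- base; up[i] <- up[i] + 1
    expect_gte(bht_cog_score(do.call(cognitive_raw, as.list(up))), s0)
  }
  expect_error(cognitive_raw(5, 0, 0, 0), "orientation_time")
  expect_error(cognitive_raw(0, 6, 0, 0), "immediate_recall")
})

test_that("cutoff classification: below positive, at-or-above negative", {
  expect_false(classify_cog(10, 10))
  expect_true(classify_cog(9, 10))
  expect_true(all(vapply(1:16, function(co) classify_cog(0, co),
                         logical(1))))
  expect_equal(classify_cog(c(0, 9, 10, 16)), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("two-stage decision composes triage and cutoff", {
  lowrisk <- risk_profile(55, "male")
  hirisk <- risk_profile(55, "male", memory_decline_subject = TRUE)
  poor <- cognitive_raw(1, 1, 3, 1)    # cog 3+0 = 3... (1+1+0+1 = 3)
  good <- cognitive_raw(4, 4, 9, 2)    # 4+4+2+2 = 12
  r1 <- two_stage_classify(lowrisk, poor)
  expect_equal(r1$decision, "low_risk_negative")
  expect_false(r1$high_risk)
  expect_true(is.na(r1$cog_score))     # cognitive test skipped
  r2 <- two_stage_classify(hirisk, poor)
  expect_equal(r2$decision, "cog_positive")
  expect_lt(r2$cog_score, 10)
  r3 <- two_stage_classify(hirisk, good)
  expect_equal(r3$decision, "cog_negative")
  # scoring is pure: identical inputs, identical outputs
  expect_identical(r2, two_stage_classify(hirisk, poor))
})

test_that("two-stage positives are a subset of cog-only positives", {
  # implies spec(two-stage) >= spec(cog-only), sens(two-stage) <= sens(cog-only)
  for (seed in 1:5) {
    coh <- random_cohort(60, seed)
    scored <- screen_cohort(coh)
    cog_pos <- scored$cog_score < 10
    two_pos <- scored$decision == "cog_positive"
    expect_true(all(!two_pos | cog_pos))
    case <- scored$group %in% c("mci", "dementia")
    if (any(case) && any(!case)) {
      sens <- function(p) sum(p & case) / sum(case)
      spec <- function(p) sum(!p & !case) / sum(!case)
      expect_lte(sens(two_pos), sens(cog_pos))
      expect_gte(spec(two_pos), spec(cog_pos))
    }
  }
})

test_that("vectorized cohort screen agrees with the scalar path", {
  coh <- random_cohort(40, 99)
  scored <- screen_cohort(coh)
  for (i in seq_len(nrow(coh))) {
    ref <- screen_row_scalar(coh[i, ])
    expect_equal(scored$risk_score[i], ref$risk_score)
    expect_equal(as.logical(scored$high_risk[i]), ref$high_risk)
    expect_equal(scored$decision[i], ref$decision)
    if (ref$high_risk) expect_equal(scored$cog_score[i], ref$cog_score)
  }
})

test_that("profile validation rejects out-of-population and non-boolean input", {
  expect_error(risk_profile(49, "male"), ">= 50")
  expect_error(risk_profile(70, "other"))
  expect_error(risk_profile(70, "male", stroke = NA), "stroke")
  expect_error(risk_profile(70, "male", depression = 2), "depression")
  # fractional age floored
  expect_equal(risk_profile(69.9, "male")$age, 69L)
})
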