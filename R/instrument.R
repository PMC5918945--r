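#' The Brain Health Test instrument
#'
#' Deterministic scoring and classification rules of the Brain Health Test
#' (BHT), a two-part dementia screening instrument for primary care:
#'
#' 1. a *risk evaluation*: a weighted risk score (RS, 1-18 points) over
#'    demographics and comorbidities, plus a high-risk triage rule that
#'    selects subjects for cognitive testing;
#' 2. a *brief cognitive test* (BHT-cog, 0-16 points): orientation to time,
#'    immediate and delayed recall of five items, and a categorical verbal
#'    fluency task (four-legged animals in one minute) binned to 0-2 points.
#'
#' The two-stage screen is the sequential conjunction of the two parts: only
#' high-risk subjects take the cognitive test, and a subject screens positive
#' iff high-risk AND BHT-cog below the cutoff (default 10).
#'
#' @name bht-instrument
NULL

#' Construct a risk profile
#'
#' Bundles one subject's answers to the risk-evaluation half of the BHT.
#' All flags are strict booleans (0/1 or TRUE/FALSE, no missing values);
#' age must be at least 50 years, the study inclusion criterion. Fractional
#' ages are floored to whole years.
#'
#' @param age age in years (>= 50).
#' @param sex `"male"` or `"female"`.
#' @param education_lt6 fewer than 6 years of formal education.
#' @param bmi_lt18 body-mass index strictly below 18. See [bmi_flag()] for a
#'   convenience converter from numeric BMI.
#' @param stroke,diabetes,hypertension,hyperlipidemia comorbidity history.
#' @param head_trauma_loc head trauma accompanied by a change of
#'   consciousness.
#' @param depression depressed mood or loss of interest/pleasure for more
#'   than two weeks.
#' @param memory_decline_subject subject self-reports memory decline.
#' @param memory_decline_informant an informant reports memory decline.
#' @param memory_impairment_doctor memory impairment noted by medical staff.
#'   Recorded for completeness; deliberately *not* used by the triage rule,
#'   whose criteria name only subject/informant reports.
#' @param needs_assistance_money_meds needs help from others to manage money
#'   or medications.
#' @return an object of class `risk_profile` (a named list).
#' @seealso [risk_score()], [is_high_risk()]
#' @export
risk_profile <- function(age, sex,
                         education_lt6 = FALSE, bmi_lt18 = FALSE,
                         stroke = FALSE, diabetes = FALSE,
                         hypertension = FALSE, hyperlipidemia = FALSE,
                         head_trauma_loc = FALSE, depression = FALSE,
                         memory_decline_subject = FALSE,
                         memory_decline_informant = FALSE,
                         memory_impairment_doctor = FALSE,
                         needs_assistance_money_meds = FALSE) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age)) {
    stop("'age' must be a single non-missing number", call. = FALSE)
  }
  age <- as.integer(floor(age))
  if (age < 50L) {
    stop("'age' must be >= 50 (study inclusion criterion), got ", age,
         call. = FALSE)
  }
  sex <- match.arg(sex, c("male", "female"))
  p <- list(
    age = age, sex = sex,
    education_lt6 = as_flag(education_lt6),
    bmi_lt18 = as_flag(bmi_lt18),
    stroke = as_flag(stroke),
    diabetes = as_flag(diabetes),
    hypertension = as_flag(hypertension),
    hyperlipidemia = as_flag(hyperlipidemia),
    head_trauma_loc = as_flag(head_trauma_loc),
    depression = as_flag(depression),
    memory_decline_subject = as_flag(memory_decline_subject),
    memory_decline_informant = as_flag(memory_decline_informant),
    memory_impairment_doctor = as_flag(memory_impairment_doctor),
    needs_assistance_money_meds = as_flag(needs_assistance_money_meds)
  )
  structure(p, class = "risk_profile")
}

#' Flag a numeric BMI as underweight
#'
#' Strict inequality: exactly 18 is not flagged.
#'
#' @param bmi numeric body-mass index.
#' @return logical vector, `TRUE` where `bmi < 18`.
#' @export
bmi_flag <- function(bmi) {
  stopifnot(is.numeric(bmi))
  bmi < 18
}

#' Age points of the risk score
#'
#' Decade bins with both edges inclusive: 50-59 scores 0, 60-69 scores 1,
#' 70-79 scores 2, 80-89 scores 3, and 90 or older scores 4. Fractional ages
#' are floored (ages are recorded in whole years).
#'
#' @param age age in years; every element must be >= 50.
#' @return integer vector of age points, 0-4.
#' @export
age_risk_points <- function(age) {
  if (!is.numeric(age) || anyNA(age)) {
    stop("'age' must be numeric with no missing values", call. = FALSE)
  }
  age <- floor(age)
  if (any(age < 50)) {
    stop("'age' must be >= 50 (study inclusion criterion)", call. = FALSE)
  }
  pmin(as.integer(age %/% 10) - 5L, 4L)
}

# table of flag weights; age and sex handled separately
.rs_flag_weights <- c(
  bmi_lt18 = 1L, education_lt6 = 1L, stroke = 1L, diabetes = 1L,
  hypertension = 1L, hyperlipidemia = 1L,
  head_trauma_loc = 3L, depression = 3L
)

#' Total risk score (RS)
#'
#' Sum of age points (0-4), sex points (male 1, female 2 — taken verbatim
#' from the instrument's weight table, which makes the minimum RS 1, not 0),
#' one point each for underweight BMI, low education, stroke, diabetes,
#' hypertension and hyperlipidemia, and three points each for head trauma
#' with consciousness change and for depression. Maximum 18.
#'
#' @param profile a [risk_profile()].
#' @return integer risk score in 1-18.
#' @export
risk_score <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  pts <- age_risk_points(profile$age) +
    (if (profile$sex == "female") 2L else 1L) +
    sum(.rs_flag_weights * vapply(names(.rs_flag_weights),
                                  function(f) profile[[f]], logical(1)))
  as.integer(pts)
}

#' High-risk triage rule
#'
#' A subject is triaged into the high-risk group (and proceeds to the
#' cognitive test) when any of three criteria holds:
#'
#' 1. subjective memory decline, whether reported by the subject or by an
#'    informant;
#' 2. needing help from others to manage money or medications;
#' 3. total risk score greater than or equal to `rs_threshold` (default 8).
#'
#' Doctor-observed memory impairment is recorded in the profile but does not
#' trigger triage.
#'
#' @param profile a [risk_profile()].
#' @param rs the subject's risk score; computed from `profile` if omitted.
#' @param rs_threshold triage threshold on the risk score, default 8.
#' @return logical: `TRUE` if high-risk.
#' @export
is_high_risk <- function(profile, rs = risk_score(profile),
                         rs_threshold = 8L) {
  stopifnot(inherits(profile, "risk_profile"))
  rs <- check_int_range(rs, 1L, 18L, "rs")
  profile$memory_decline_subject || profile$memory_decline_informant ||
    profile$needs_assistance_money_meds || rs >= rs_threshold
}

#' Construct raw cognitive responses
#'
#' Raw item responses feeding the BHT-cog score. The verbal fluency count is
#' the number of four-legged animals named in one minute and is unbounded
#' above; the other items have closed ranges.
#'
#' @param orientation_time orientation to time, 0-4.
#' @param immediate_recall immediate recall of five items, 0-5.
#' @param fluency_count verbal fluency count, >= 0.
#' @param delayed_recall delayed recall of five items, 0-5.
#' @return an object of class `cognitive_raw`.
#' @export
cognitive_raw <- function(orientation_time, immediate_recall,
                          fluency_count, delayed_recall) {
  structure(list(
    orientation_time = check_int_range(orientation_time, 0L, 4L),
    immediate_recall = check_int_range(immediate_recall, 0L, 5L),
    fluency_count = check_int_range(fluency_count, 0L, Inf),
    delayed_recall = check_int_range(delayed_recall, 0L, 5L)
  ), class = "cognitive_raw")
}

#' Verbal fluency points
#'
#' Bins the one-minute fluency count into the 0-2 points contributed to the
#' BHT-cog: counts below 5 score 0, counts 5 through 8 score 1, and counts
#' of 9 or more score 2. The bin boundaries come from the healthy and
#' dementia group means of the fluency task in the development cohort
#' (9.5 and 4.7 animals).
#'
#' @param fluency_count integer vector of counts, each >= 0.
#' @return integer vector of points in 0-2.
#' @export
fluency_points <- function(fluency_count) {
  if (!is.numeric(fluency_count) || anyNA(fluency_count) ||
      any(fluency_count < 0) || any(fluency_count != trunc(fluency_count))) {
    stop("'fluency_count' must be non-negative integers", call. = FALSE)
  }
  ifelse(fluency_count < 5, 0L, ifelse(fluency_count <= 8, 1L, 2L))
}

#' BHT-cog total score
#'
#' Sum of orientation to time (0-4), immediate recall (0-5), binned verbal
#' fluency (0-2) and delayed recall (0-5); total 0-16. The Clock Drawing
#' Test is deliberately absent from the finalized instrument (it had a high
#' non-completion rate in the development cohort).
#'
#' @param raw a [cognitive_raw()].
#' @return integer score in 0-16.
#' @export
bht_cog_score <- function(raw) {
  stopifnot(inherits(raw, "cognitive_raw"))
  as.integer(raw$orientation_time + raw$immediate_recall +
               fluency_points(raw$fluency_count) + raw$delayed_recall)
}

#' Classify a BHT-cog score at a cutoff
#'
#' Scores *below* the cutoff screen positive; scores at or above it screen
#' negative. The published operating cutoff is 10.
#'
#' @param score integer BHT-cog score(s), 0-16.
#' @param cutoff integer cutoff, 1-16 (default 10).
#' @return logical vector: `TRUE` = screen positive.
#' @export
classify_cog <- function(score, cutoff = 10L) {
  if (!is.numeric(score) || anyNA(score) || any(score < 0) || any(score > 16)) {
    stop("'score' must be in 0-16 with no missing values", call. = FALSE)
  }
  cutoff <- check_int_range(cutoff, 1L, 16L, "cutoff")
  score < cutoff
}

#' Two-stage screening decision
#'
#' Applies the full BHT: the triage gate first, then the cognitive test.
#' Low-risk subjects screen negative without taking the cognitive test
#' (`cog_score` is `NA`); high-risk subjects screen positive iff their
#' BHT-cog score is below the cutoff. The positive set is therefore the
#' conjunction *high-risk AND cog < cutoff*, so relative to the cognitive
#' test alone the two-stage screen can only gain specificity and lose
#' sensitivity.
#'
#' @param profile a [risk_profile()].
#' @param raw a [cognitive_raw()], consulted only when the subject is
#'   high-risk.
#' @param cutoff BHT-cog cutoff, default 10.
#' @param rs_threshold triage risk-score threshold, default 8.
#' @return an object of class `screening_result`: a list with
#'   `risk_score`, `high_risk`, `cog_score` (`NA` when triage-negative) and
#'   `decision`, one of `"low_risk_negative"`, `"cog_negative"`,
#'   `"cog_positive"`.
#' @export
two_stage_classify <- function(profile, raw, cutoff = 10L,
                               rs_threshold = 8L) {
  rs <- risk_score(profile)
  hr <- is_high_risk(profile, rs, rs_threshold)
  if (!hr) {
    res <- list(risk_score = rs, high_risk = FALSE, cog_score = NA_integer_,
                decision = "low_risk_negative")
  } else {
    cs <- bht_cog_score(raw)
    res <- list(risk_score = rs, high_risk = TRUE, cog_score = cs,
                decision = if (classify_cog(cs, cutoff)) "cog_positive"
                           else "cog_negative")
  }
  structure(res, class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("BHT screening result\n")
  cat(sprintf("  risk score: %d  high risk: %s\n", x$risk_score, x$high_risk))
  if (x$high_risk) cat(sprintf("  BHT-cog:    %d\n", x$cog_score))
  cat(sprintf("  decision:   %s\n", x$decision))
  invisible(x)
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("BHT risk profile: %s, age %d\n", x$sex, x$age))
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  cat("  factors:", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
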