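#' Vectorized instrument scoring over a cohort
#'
#' Cohort-level counterparts of the scalar scoring operations, used by the
#' command-line tools and the validation report. They apply exactly the
#' same rules as [risk_score()], [is_high_risk()], [bht_cog_score()] and
#' [two_stage_classify()], row by row.
#'
#' @name bht-screen
NULL

#' Risk score for every cohort row
#'
#' @param cohort a cohort data.frame.
#' @return integer vector of risk scores (1-18).
#' @export
risk_score_vec <- function(cohort) {
  pts <- age_risk_points(cohort$age) +
    ifelse(cohort$sex == "female", 2L, 1L)
  for (f in names(.rs_flag_weights)) {
    pts <- pts + .rs_flag_weights[[f]] * as.integer(cohort[[f]])
  }
  as.integer(pts)
}

#' BHT-cog total for every cohort row
#'
#' @param cohort a cohort data.frame.
#' @return integer vector of scores (0-16).
#' @export
bht_cog_score_vec <- function(cohort) {
  as.integer(cohort$orientation_time + cohort$immediate_recall +
               fluency_points(cohort$fluency_count) + cohort$delayed_recall)
}

#' Score and classify a whole cohort
#'
#' Appends `risk_score`, `high_risk`, `cog_score` and `decision` columns.
#' `cog_score` is reported for every row (the raw items are in the data
#' anyway) but the `decision` column respects the two-stage semantics:
#' triage-negative subjects are `low_risk_negative` regardless of their
#' cognitive score.
#'
#' @param cohort a cohort data.frame.
#' @param cutoff BHT-cog cutoff (default 10).
#' @param rs_threshold triage risk-score threshold (default 8).
#' @return the cohort with four appended columns.
#' @export
screen_cohort <- function(cohort, cutoff = 10L, rs_threshold = 8L) {
  cohort <- as.data.frame(cohort)
  rs <- risk_score_vec(cohort)
  hr <- as.logical(cohort$memory_decline_subject) |
    as.logical(cohort$memory_decline_informant) |
    as.logical(cohort$needs_assistance_money_meds) |
    rs >= rs_threshold
  cs <- bht_cog_score_vec(cohort)
  cohort$risk_score <- rs
  cohort$high_risk <- as.integer(hr)
  cohort$cog_score <- cs
  cohort$decision <- ifelse(!hr, "low_risk_negative",
                            ifelse(cs < cutoff, "cog_positive",
                                   "cog_negative"))
  cohort
}
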