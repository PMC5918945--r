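#' Packaged development-cohort summary fixtures
#'
#' The package ships the printed summary statistics of the instrument's
#' development cohort (813 memory-clinic subjects: 166 healthy, 225 MCI,
#' 422 dementia) as in-code fixtures, so validation arithmetic can be
#' reproduced without any external download. Counts are encoded exactly as
#' printed, with one documented correction: the healthy-group hypertension
#' count is printed as "930 (56%)", which is internally inconsistent with
#' n = 166; it is encoded as 93 (93/166 = 56.0%).
#'
#' @name bht-fixtures
NULL

# Table-1-style per-group factor counts. Rows are risk-factor / complaint
# names matching the cohort CSV schema, columns the three groups.
.table1_counts <- function() {
  m <- rbind(
    education_lt6               = c(20, 36, 117),
    memory_decline_subject      = c(62, 163, 286),
    memory_decline_informant    = c(39, 141, 362),
    memory_decline_any          = c(72, 209, 405),
    memory_impairment_doctor    = c(16, 24, 76),
    bmi_lt18                    = c(7, 10, 18),
    stroke                      = c(22, 37, 72),
    diabetes                    = c(41, 64, 124),
    hypertension                = c(93, 121, 238),  # printed "930", corrected
    hyperlipidemia              = c(44, 61, 108),
    head_trauma_loc             = c(6, 13, 44),
    needs_assistance_money_meds = c(9, 47, 262),
    depression                  = c(14, 33, 120),
    female                      = c(87, 119, 239)
  )
  colnames(m) <- c("healthy", "mci", "dementia")
  m
}

#' Development-cohort characteristics (group sizes, factor counts)
#'
#' Returns the published per-group risk-factor counts as a
#' [cohort_summary] object. The `memory_decline_any` row is the printed
#' "subjects or informants" pooled count (not the union of the two separate
#' rows, which the publication does not give subject-level data to form).
#'
#' @return a `cohort_summary` with fields `n` (named group sizes),
#'   `factor_counts`, `factor_pct`, `age` (per-group mean/sd),
#'   `dementia_subtypes` (named counts within the dementia group, AD = 320),
#'   and `excluded_n = 54` (subjects dropped for incomplete data).
#' @export
fixtures_table1 <- function() {
  n <- c(healthy = 166L, mci = 225L, dementia = 422L)
  counts <- .table1_counts()
  structure(list(
    n = n,
    factor_counts = counts,
    factor_pct = sweep(counts, 2, n, "/"),
    age = list(mean = c(healthy = 72.3, mci = 73.3, dementia = 79.0),
               sd = c(healthy = 8.4, mci = 8.7, dementia = 8.4)),
    mmse = list(mean = c(healthy = 27.9, mci = 24.6, dementia = 16.8),
                sd = c(healthy = 2.1, mci = 3.8, dementia = 6.3)),
    dementia_subtypes = c(ad = 320L, vascular = 33L, lewy_body = 7L,
                          parkinson = 9L, frontotemporal = 7L, mixed = 46L),
    excluded_n = 54L
  ), class = "cohort_summary")
}

#' Risk-score weight table
#'
#' The published weights: age decade bins 0-4 points, sex (male 1,
#' female 2), 1 point per ordinary comorbidity, 3 points each for head
#' trauma with consciousness change and depression; total 18.
#'
#' @return a list with `age_bins` (data.frame of bin edges and points),
#'   `sex` (named vector) and `flags` (named vector of flag weights).
#' @export
fixtures_risk_weights <- function() {
  list(
    age_bins = data.frame(
      lo = c(50L, 60L, 70L, 80L, 90L),
      hi = c(59L, 69L, 79L, 89L, NA),
      points = 0:4
    ),
    sex = c(male = 1L, female = 2L),
    flags = .rs_flag_weights
  )
}

#' Per-group cognitive item statistics (original instrument)
#'
#' Published mean and SD of each raw cognitive item by diagnostic group
#' (all-education rows). The fluency entry is the raw one-minute count,
#' before binning.
#'
#' @return a list of per-item lists, each with named `mean` and `sd`
#'   vectors over `healthy`, `mci`, `dementia`.
#' @export
fixtures_item_stats <- function() {
  g <- c("healthy", "mci", "dementia")
  stat <- function(means, sds) {
    list(mean = stats::setNames(means, g), sd = stats::setNames(sds, g))
  }
  list(
    orientation_time = stat(c(3.7, 3.2, 1.2), c(0.7, 1.1, 1.3)),
    immediate_recall = stat(c(3.6, 3.2, 1.9), c(1.2, 1.2, 1.4)),
    fluency_count    = stat(c(9.5, 8.2, 4.7), c(3.3, 3.2, 3.2)),
    delayed_recall   = stat(c(3.6, 2.6, 1.0), c(1.4, 1.6, 1.4))
  )
}

#' Per-group totals of the finalized 16-point cognitive test
#'
#' Published mean and SD of the finalized BHT-cog total score by group
#' (all-education rows): 12.5 +/- 2.6 healthy, 10.3 +/- 2.9 MCI,
#' 4.7 +/- 3.3 dementia.
#'
#' @return a list with named `mean` and `sd` vectors.
#' @export
fixtures_cog_totals <- function() {
  g <- c("healthy", "mci", "dementia")
  list(mean = stats::setNames(c(12.5, 10.3, 4.7), g),
       sd = stats::setNames(c(2.6, 2.9, 3.3), g))
}

#' Published triage bookkeeping counts
#'
#' The high-risk triage counts reported for the development cohort: 89 of
#' 166 healthy subjects triaged high-risk, 8 of 225 MCI and 4 of 422
#' dementia patients triaged low-risk (i.e. missed).
#'
#' @return a list with `high_risk_healthy`, `low_risk_mci`,
#'   `low_risk_dementia` and the group sizes.
#' @export
fixtures_triage_counts <- function() {
  list(
    n = c(healthy = 166L, mci = 225L, dementia = 422L),
    high_risk_healthy = 89L,
    low_risk_mci = 8L,
    low_risk_dementia = 4L
  )
}
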