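# Independent oracles and fixture builders shared across test files.

# Brute-force tie-corrected Mann-Whitney AUC: with positive_low, counts
# P(score_case < score_control) + P(tie)/2 over all case-control pairs.
# Deliberately quadratic and independent of the roc_curve implementation.
mw_auc <- function(scores, labels, positive_low = TRUE) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (positive_low) {
        (p < q) + 0.5 * (p == q)
      } else {
        (p > q) + 0.5 * (p == q)
      }
    }
  }
  tot / (length(pos) * length(neg))
}

# one fully-specified schema-valid cohort row
make_row <- function(subject_id = "s1", group = "healthy", age = 70,
                     sex = "female", flags = 0, orientation_time = 3,
                     immediate_recall = 3, fluency_count = 8,
                     delayed_recall = 3, mmse = NA, cdr = NA, ...) {
  row <- data.frame(
    subject_id = subject_id, group = group, age = age, sex = sex,
    education_lt6 = flags, bmi_lt18 = flags, stroke = flags,
    diabetes = flags, hypertension = flags, hyperlipidemia = flags,
    head_trauma_loc = flags, depression = flags,
    memory_decline_subject = flags, memory_decline_informant = flags,
    memory_impairment_doctor = flags, needs_assistance_money_meds = flags,
    orientation_time = orientation_time, immediate_recall = immediate_recall,
    fluency_count = fluency_count, delayed_recall = delayed_recall,
    mmse = mmse, cdr = cdr,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) row[[nm]] <- dots[[nm]]
  row
}

# random schema-valid cohort with both impaired and healthy subjects
random_cohort <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_row(
      subject_id = sprintf("r%03d", i),
      group = sample(c("healthy", "mci", "dementia"), 1),
      age = sample(50:99, 1),
      sex = sample(c("male", "female"), 1),
      orientation_time = sample(0:4, 1),
      immediate_recall = sample(0:5, 1),
      fluency_count = sample(0:20, 1),
      delayed_recall = sample(0:5, 1),
      education_lt6 = rbinom(1, 1, 0.3),
      bmi_lt18 = rbinom(1, 1, 0.1),
      stroke = rbinom(1, 1, 0.2),
      diabetes = rbinom(1, 1, 0.3),
      hypertension = rbinom(1, 1, 0.5),
      hyperlipidemia = rbinom(1, 1, 0.3),
      head_trauma_loc = rbinom(1, 1, 0.1),
      depression = rbinom(1, 1, 0.2),
      memory_decline_subject = rbinom(1, 1, 0.5),
      memory_decline_informant = rbinom(1, 1, 0.5),
      memory_impairment_doctor = rbinom(1, 1, 0.1),
      needs_assistance_money_meds = rbinom(1, 1, 0.3)
    )
  }))
}

# scalar-path reference for the vectorized screen, via the public scalar API
screen_row_scalar <- function(row, cutoff = 10L, rs_threshold = 8L) {
  prof <- risk_profile(
    age = row$age, sex = row$sex,
    education_lt6 = row$education_lt6, bmi_lt18 = row$bmi_lt18,
    stroke = row$stroke, diabetes = row$diabetes,
    hypertension = row$hypertension, hyperlipidemia = row$hyperlipidemia,
    head_trauma_loc = row$head_trauma_loc, depression = row$depression,
    memory_decline_subject = row$memory_decline_subject,
    memory_decline_informant = row$memory_decline_informant,
    memory_impairment_doctor = row$memory_impairment_doctor,
    needs_assistance_money_meds = row$needs_assistance_money_meds
  )
  raw <- cognitive_raw(row$orientation_time, row$immediate_recall,
                       row$fluency_count, row$delayed_recall)
  two_stage_classify(prof, raw, cutoff = cutoff, rs_threshold = rs_threshold)
}
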