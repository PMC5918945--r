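#' Cohort validation report
#'
#' Runs the full diagnostic evaluation of the instrument on a labeled
#' cohort: confusion metrics at the operating cutoff for both the
#' cognitive test alone and the two-stage screen, ROC/AUC with confidence
#' intervals for the three standard contrasts (dementia vs healthy,
#' dementia vs MCI, impaired vs healthy), Youden-optimal cutoffs, an
#' odds-ratio table for the four headline risk factors, and
#' education-stratified sub-reports (strata with fewer than 10 subjects
#' are flagged unstable).
#'
#' @param cohort a labeled cohort data.frame (groups among healthy / mci /
#'   dementia).
#' @param cutoff BHT-cog cutoff, default 10.
#' @param rs_threshold triage risk-score threshold, default 8.
#' @return a list of class `validation_report`.
#' @export
validate_cohort <- function(cohort, cutoff = 10L, rs_threshold = 8L) {
  cohort <- as.data.frame(cohort)
  groups <- unique(cohort$group)
  if (length(intersect(groups, c("healthy", "mci", "dementia"))) < 2) {
    stop("need at least two labeled groups for validation", call. = FALSE)
  }
  scored <- screen_cohort(cohort, cutoff, rs_threshold)

  contrasts <- list(
    dementia_vs_healthy = c(case = "dementia", control = "healthy"),
    dementia_vs_mci = c(case = "dementia", control = "mci"),
    impaired_vs_healthy = c(case = "impaired", control = "healthy")
  )
  in_set <- function(g, set) {
    if (set == "impaired") g %in% c("mci", "dementia") else g == set
  }
  eval_contrast <- function(sub, case) {
    list(
      n_case = sum(case), n_control = sum(!case),
      cog_only = with(sub, confusion_metrics(
        tp = sum(case & cog_score < cutoff),
        fp = sum(!case & cog_score < cutoff),
        tn = sum(!case & cog_score >= cutoff),
        fn = sum(case & cog_score >= cutoff))),
      two_stage = with(sub, confusion_metrics(
        tp = sum(case & decision == "cog_positive"),
        fp = sum(!case & decision == "cog_positive"),
        tn = sum(!case & decision != "cog_positive"),
        fn = sum(case & decision != "cog_positive"))),
      roc = tryCatch({
        r <- roc_curve(sub$cog_score, case, positive_low = TRUE)
        list(auc = r$auc, auc_ci = r$auc_ci,
             optimal = optimal_cutoff(r))
      }, error = function(e) NULL)
    )
  }

  roc_section <- list()
  for (cn in names(contrasts)) {
    cc <- contrasts[[cn]]
    keep <- if (cc[["case"]] == "impaired") {
      scored$group %in% c("mci", "dementia", cc[["control"]])
    } else scored$group %in% cc
    sub <- scored[keep, , drop = FALSE]
    case <- in_set(sub$group, cc[["case"]])
    if (sum(case) == 0 || sum(!case) == 0) next
    roc_section[[cn]] <- eval_contrast(sub, case)
  }

  headline_factors <- c("memory_decline_any", "needs_assistance_money_meds",
                        "head_trauma_loc", "depression")
  or_section <- NULL
  if (all(c("healthy") %in% groups) && any(groups %in% c("mci", "dementia"))) {
    coh2 <- cohort
    coh2$memory_decline_any <- as.integer(
      as.logical(cohort$memory_decline_subject) |
        as.logical(cohort$memory_decline_informant))
    imp <- intersect(c("mci", "dementia"), groups)
    or_section <- lapply(headline_factors, function(f) {
      o <- tryCatch(odds_ratio_woolf(build_2x2(coh2, f, imp)),
                    error = function(e) NULL)
      if (is.null(o)) return(NULL)
      list(factor = f, or = o$or, ci_lo = o$ci_lo, ci_hi = o$ci_hi,
           corrected = o$corrected)
    })
    names(or_section) <- headline_factors
    or_section <- Filter(Negate(is.null), or_section)
  }

  strata <- list()
  for (s in c("edu_lt6", "edu_ge6")) {
    keep <- if (s == "edu_lt6") cohort$education_lt6 == 1
            else cohort$education_lt6 == 0
    sub <- scored[keep, , drop = FALSE]
    case <- sub$group == "dementia"
    if (sum(case) == 0 || sum(sub$group == "healthy") == 0) next
    sub2 <- sub[sub$group %in% c("healthy", "dementia"), , drop = FALSE]
    strata[[s]] <- c(eval_contrast(sub2, sub2$group == "dementia"),
                     list(unstable = nrow(sub2) < 10 ||
                            min(sum(sub2$group == "dementia"),
                                sum(sub2$group == "healthy")) < 10))
  }

  structure(list(
    cutoff = cutoff, rs_threshold = rs_threshold,
    n = stats::setNames(
      vapply(groups, function(g) sum(cohort$group == g), integer(1)), groups),
    contrasts = roc_section,
    odds_ratios = or_section,
    education_strata = strata
  ), class = "validation_report")
}

# flatten a report to the plain list written as JSON / printed as text
report_to_list <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  cm <- function(m) list(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
                         sensitivity = m$sensitivity,
                         specificity = m$specificity,
                         ppv = m$ppv, npv = m$npv)
  contr <- lapply(report$contrasts, function(x) {
    out <- list(n_case = x$n_case, n_control = x$n_control,
                cog_only = cm(x$cog_only), two_stage = cm(x$two_stage))
    if (!is.null(x$roc)) {
      out$auc <- x$roc$auc
      out$auc_ci <- x$roc$auc_ci
      out$optimal_cutoff <- x$roc$optimal$threshold
      out$youden_j <- x$roc$optimal$J
    }
    out
  })
  strata <- lapply(report$education_strata, function(x) {
    list(n_case = x$n_case, n_control = x$n_control,
         cog_only = cm(x$cog_only), two_stage = cm(x$two_stage),
         auc = if (!is.null(x$roc)) x$roc$auc else NULL,
         unstable = x$unstable)
  })
  list(cutoff = report$cutoff, rs_threshold = report$rs_threshold,
       n = as.list(report$n), contrasts = contr,
       odds_ratios = report$odds_ratios, education_strata = strata)
}

#' Render a validation report
#'
#' @param report a `validation_report`.
#' @param format `"text"` or `"json"`; both carry identical numbers.
#' @return a character vector of lines (text) or a JSON string.
#' @export
render_report <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  lst <- report_to_list(report)
  if (format == "json") {
    return(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null"))
  }
  pct <- function(p) if (is.na(p)) "undef" else sprintf("%.1f%%", fmt_pct(p))
  lines <- c(sprintf("BHT validation report (cutoff %d, RS threshold %d)",
                     lst$cutoff, lst$rs_threshold),
             paste("groups:", paste(sprintf("%s=%d", names(lst$n),
                                            unlist(lst$n)), collapse = " ")))
  for (cn in names(lst$contrasts)) {
    x <- lst$contrasts[[cn]]
    lines <- c(lines, sprintf("[%s] cases=%d controls=%d", cn, x$n_case,
                              x$n_control))
    for (mode in c("cog_only", "two_stage")) {
      m <- x[[mode]]
      lines <- c(lines, sprintf(
        "  %-9s sens=%s spec=%s ppv=%s npv=%s", mode,
        pct(m$sensitivity), pct(m$specificity), pct(m$ppv), pct(m$npv)))
    }
    if (!is.null(x$auc)) {
      lines <- c(lines, sprintf(
        "  AUC=%.6f (95%% CI %.6f-%.6f), optimal cutoff %d (J=%.6f)",
        x$auc, x$auc_ci[1], x$auc_ci[2], x$optimal_cutoff, x$youden_j))
    }
  }
  if (length(lst$odds_ratios)) {
    lines <- c(lines, "odds ratios (impaired vs healthy, Woolf 95% CI):")
    for (f in names(lst$odds_ratios)) {
      o <- lst$odds_ratios[[f]]
      lines <- c(lines, sprintf("  %-28s OR=%.6f CI=%.6f-%.6f%s", f, o$or,
                                o$ci_lo, o$ci_hi,
                                if (isTRUE(o$corrected)) " [0.5-corrected]"
                                else ""))
    }
  }
  for (s in names(lst$education_strata)) {
    x <- lst$education_strata[[s]]
    lines <- c(lines, sprintf(
      "[stratum %s] cases=%d controls=%d%s", s, x$n_case, x$n_control,
      if (isTRUE(x$unstable)) " (UNSTABLE: n < 10)" else ""))
    m <- x$cog_only
    lines <- c(lines, sprintf("  cog_only  sens=%s spec=%s ppv=%s npv=%s",
                              pct(m$sensitivity), pct(m$specificity),
                              pct(m$ppv), pct(m$npv)))
    if (!is.null(x$auc)) lines <- c(lines, sprintf("  AUC=%.6f", x$auc))
  }
  lines
}
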