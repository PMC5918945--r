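#' Diagnostic-evaluation statistics
#'
#' Closed-form statistics used to validate a screening instrument against a
#' reference diagnosis: 2x2 confusion-matrix metrics, odds ratios with
#' Woolf (logit) confidence intervals, ROC curves with trapezoidal AUC and
#' Hanley-McNeil intervals, and Youden-optimal cutoffs.
#'
#' @name bht-validation
NULL

#' Construct a 2x2 contingency table
#'
#' Exposure by outcome counts for odds-ratio analysis:
#' `a` exposed-impaired, `b` unexposed-impaired, `c` exposed-healthy,
#' `d` unexposed-healthy.
#'
#' @param a,b,c,d non-negative integer counts; their sum must be positive.
#' @return an object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!is.numeric(cells) || anyNA(cells) || any(cells < 0) ||
      any(cells != trunc(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("table is empty (all cells zero)", call. = FALSE)
  structure(list(a = as.integer(cells[["a"]]), b = as.integer(cells[["b"]]),
                 c = as.integer(cells[["c"]]), d = as.integer(cells[["d"]])),
            class = "contingency_2x2")
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive value from
#' raw classification counts. A metric whose denominator is zero is
#' returned as `NA` and named in the `undefined` field — never silently
#' reported as 0.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return an object of class `confusion_metrics`: the four counts, the
#'   four proportions in \[0,1\], and `undefined`, a character vector of
#'   metric names with zero denominators.
#' @examples
#' m <- confusion_metrics(tp = 635, fp = 89, tn = 77, fn = 12)
#' round_half_up(100 * m$sensitivity)  # 98.1
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != trunc(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  m <- list(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
  m$undefined <- names(which(vapply(
    m[c("sensitivity", "specificity", "ppv", "npv")], is.na, logical(1))))
  structure(m, class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, digits = 1, ...) {
  cat(sprintf("confusion metrics (tp=%d fp=%d tn=%d fn=%d)\n",
              x$tp, x$fp, x$tn, x$fn))
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    val <- if (is.na(x[[nm]])) "undefined"
           else sprintf("%.*f%%", digits, fmt_pct(x[[nm]], digits))
    cat(sprintf("  %-11s %s\n", nm, val))
  }
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c) with the Woolf (logit) interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to every cell before
#' computing, and the result is flagged via `corrected = TRUE`. A table
#' with an all-zero margin (a+b, c+d, a+c or b+d equal to zero) has no
#' defined odds ratio and is an error.
#'
#' @param table a [contingency_2x2()].
#' @param alpha two-sided significance level, default 0.05 for a 95\% CI.
#' @return a list of class `odds_ratio`: `or`, `ci_lo`, `ci_hi`,
#'   `corrected`, `alpha`.
#' @examples
#' # memory decline (subject or informant), impaired vs healthy
#' odds_ratio_woolf(contingency_2x2(614, 33, 72, 94))
#' @export
odds_ratio_woolf <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$a, table$b, table$c, table$d)
  margins <- c(cells[1] + cells[2], cells[3] + cells[4],
               cells[1] + cells[3], cells[2] + cells[4])
  if (any(margins == 0)) {
    stop("odds ratio undefined: a table margin is zero", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    or = or,
    ci_lo = exp(log(or) - z * se),
    ci_hi = exp(log(or) + z * se),
    corrected = corrected,
    alpha = alpha
  ), class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, digits = 1, ...) {
  cat(sprintf("OR %.*f, %d%% CI %.*f-%.*f (Woolf)%s\n",
              digits, round_half_up(x$or, digits),
              round(100 * (1 - x$alpha)),
              digits, round_half_up(x$ci_lo, digits),
              digits, round_half_up(x$ci_hi, digits),
              if (x$corrected) " [Haldane-Anscombe 0.5 correction]" else ""))
  invisible(x)
}

#' ROC curve for an integer-valued screening score
#'
#' Sweeps every threshold over the score range. With `positive_low = TRUE`
#' (the BHT convention: impaired subjects score *low*), a subject is called
#' positive at threshold t iff `score < t`; thresholds run from `min(score)`
#' (nobody positive) to `max(score) + 1` (everybody positive), so the curve
#' always spans (0,0) to (1,1). The AUC is the trapezoidal area, which for
#' this construction equals the tie-corrected Mann-Whitney probability
#' `P(score_case < score_control) + P(tie)/2`. The AUC confidence interval
#' uses the Hanley-McNeil variance approximation (the development study
#' does not name its method; treat as approximate).
#'
#' @param scores integer vector of scores.
#' @param labels logical (or 0/1) vector: `TRUE` = case (impaired).
#' @param positive_low if `TRUE` (default) low scores indicate impairment.
#' @param alpha significance level for the AUC CI, default 0.05.
#' @return an object of class `roc_curve`: `thresholds`, `points` (a
#'   data.frame with `fpr`, `tpr` and per-threshold counts), `auc`,
#'   `auc_ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive_low = TRUE, alpha = 0.05) {
  if (!is.numeric(scores) || anyNA(scores)) {
    stop("'scores' must be numeric with no missing values", call. = FALSE)
  }
  labels <- as.logical(labels)
  if (anyNA(labels) || length(labels) != length(scores)) {
    stop("'labels' must be 0/1 or logical, same length as 'scores'",
         call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one case and one control", call. = FALSE)
  }
  # orient so that larger oriented score = more case-like
  s <- if (positive_low) -scores else scores
  thr <- seq(min(scores), max(scores) + 1L)
  pos_at <- function(t) if (positive_low) scores < t else scores >= t
  pts <- vapply(thr, function(t) {
    p <- pos_at(t)
    c(tp = sum(p & labels), fp = sum(p & !labels))
  }, numeric(2))
  points <- data.frame(
    threshold = thr,
    tp = pts["tp", ], fp = pts["fp", ],
    fpr = pts["fp", ] / n_neg,
    tpr = pts["tp", ] / n_pos
  )
  points <- points[order(points$fpr, points$tpr), ]
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  # Hanley-McNeil SE of the AUC
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    thresholds = thr,
    points = points,
    auc = auc,
    auc_ci = c(max(0, auc - z * se), min(1, auc + z * se)),
    n_pos = n_pos, n_neg = n_neg,
    positive_low = positive_low
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cases vs %d controls, %d thresholds\n",
              x$n_pos, x$n_neg, length(x$thresholds)))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Returns the threshold maximizing Youden's J = sensitivity +
#' specificity - 1. Ties are broken toward the lower threshold, which for
#' a positive-low score means the more specific operating point.
#'
#' @param roc a [roc_curve()].
#' @return a list: `threshold`, `J`, `sensitivity`, `specificity`,
#'   `criterion = "youden"`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  J <- p$tpr - p$fpr
  # order by threshold so which.max's first-hit rule breaks ties low
  o <- order(p$threshold)
  i <- o[which.max(J[o])]
  list(threshold = p$threshold[i], J = J[i],
       sensitivity = p$tpr[i], specificity = 1 - p$fpr[i],
       criterion = "youden")
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with explicit preconditions: equal lengths of at
#' least 3 and non-zero variance in both vectors (zero variance is an
#' error, not a silent `NA`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Build a 2x2 exposure table from a cohort or cohort summary
#'
#' Pools the named diagnostic groups as "impaired" against the healthy
#' group, and splits by presence of a risk factor: `a` = impaired with the
#' factor, `b` = impaired without, `c` = healthy with, `d` = healthy
#' without.
#'
#' @param x a cohort data frame (from [read_cohort()] or
#'   [simulate_cohort()]) or a [cohort_summary] (e.g. [fixtures_table1()]).
#' @param factor name of the risk-factor column/row, e.g.
#'   `"needs_assistance_money_meds"`.
#' @param impaired_groups character vector of group labels pooled as
#'   impaired, default `c("mci", "dementia")`.
#' @return a [contingency_2x2()].
#' @export
build_2x2 <- function(x, factor, impaired_groups = c("mci", "dementia")) {
  impaired_groups <- tolower(impaired_groups)
  if (inherits(x, "cohort_summary")) {
    groups <- names(x$n)
    if (!all(impaired_groups %in% groups)) {
      stop("unknown group(s): ",
           paste(setdiff(impaired_groups, groups), collapse = ", "),
           call. = FALSE)
    }
    if (!factor %in% rownames(x$factor_counts)) {
      stop("unknown factor: ", factor, call. = FALSE)
    }
    cnt <- x$factor_counts[factor, ]
    a <- sum(cnt[impaired_groups])
    c_ <- sum(cnt["healthy"])
    n_imp <- sum(x$n[impaired_groups])
    n_hea <- x$n[["healthy"]]
  } else {
    x <- as.data.frame(x)
    if (!factor %in% names(x)) stop("unknown factor: ", factor, call. = FALSE)
    if (!all(impaired_groups %in% unique(x$group))) {
      stop("unknown group(s): ",
           paste(setdiff(impaired_groups, unique(x$group)), collapse = ", "),
           call. = FALSE)
    }
    imp <- x$group %in% impaired_groups
    hea <- x$group == "healthy"
    f <- as.logical(x[[factor]])
    a <- sum(imp & f); n_imp <- sum(imp)
    c_ <- sum(hea & f); n_hea <- sum(hea)
  }
  contingency_2x2(a = a, b = n_imp - a, c = c_, d = n_hea - c_)
}
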