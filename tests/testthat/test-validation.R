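test_that("confusion metrics compute the four ratios and flag undefined ones", {
  m <- confusion_metrics(tp = 3, fp = 1, tn = 2, fn = 2)
  expect_equal(round_half_up(100 * m$sensitivity), 60.0)
  expect_equal(round_half_up(100 * m$specificity), 66.7)
  expect_equal(round_half_up(100 * m$ppv), 75.0)
  expect_equal(round_half_up(100 * m$npv), 50.0)
  expect_length(m$undefined, 0)
  # perfect classifier
  p <- confusion_metrics(tp = 5, fp = 0, tn = 7, fn = 0)
  expect_equal(c(p$sensitivity, p$specificity, p$ppv, p$npv), rep(1, 4))
  # zero denominators flagged, never silently 0
  u <- confusion_metrics(tp = 0, fp = 0, tn = 3, fn = 2)
  expect_true(is.na(u$ppv))
  expect_true("ppv" %in% u$undefined)
  expect_error(confusion_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("confusion metrics are Bayes-consistent at the cohort prevalence", {
  set.seed(21)
  for (i in 1:20) {
    tp <- sample(1:50, 1); fp <- sample(1:50, 1)
    tn <- sample(1:50, 1); fn <- sample(1:50, 1)
    m <- confusion_metrics(tp, fp, tn, fn)
    prev <- (tp + fn) / (tp + fp + tn + fn)
    expect_equal(m$ppv,
                 m$sensitivity * prev /
                   (m$sensitivity * prev + (1 - m$specificity) * (1 - prev)))
  }
})

test_that("Woolf odds ratios reproduce the published values and CIs", {
  # (a, b, c, d) -> printed OR, CI
  cases <- list(
    list(t = c(614, 33, 72, 94), or = 24.3, ci = c(15.2, 38.7)),
    list(t = c(309, 338, 9, 157), or = 15.9, ci = c(8.0, 31.8)),
    list(t = c(57, 590, 6, 160), or = 2.6, ci = c(1.1, 6.1)),
    list(t = c(153, 494, 14, 152), or = 3.4, ci = c(1.9, 6.0))
  )
  for (cs in cases) {
    o <- odds_ratio_woolf(do.call(contingency_2x2, as.list(cs$t)))
    expect_equal(round_half_up(o$or), cs$or)
    expect_equal(round_half_up(c(o$ci_lo, o$ci_hi)), cs$ci)
    expect_false(o$corrected)
  }
  # symmetric table
  expect_equal(odds_ratio_woolf(contingency_2x2(10, 10, 10, 10))$or, 1.0)
})

test_that("zero cells take the Haldane-Anscombe correction and are flagged", {
  o <- odds_ratio_woolf(contingency_2x2(5, 0, 3, 7))
  expect_true(o$corrected)
  # hand value: (5.5 * 7.5) / (0.5 * 3.5)
  expect_equal(o$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_equal(round_half_up(o$or), 23.6)
  # all-zero margin is undefined
  expect_error(odds_ratio_woolf(contingency_2x2(0, 0, 3, 7)), "margin")
})

test_that("exposure swap inverts the odds ratio", {
  set.seed(5)
  for (i in 1:25) {
    t <- sample(1:40, 4, replace = TRUE)
    o1 <- odds_ratio_woolf(contingency_2x2(t[1], t[2], t[3], t[4]))$or
    o2 <- odds_ratio_woolf(contingency_2x2(t[2], t[1], t[4], t[3]))$or
    expect_equal(o1 * o2, 1)
  }
})

test_that("ROC endpoints, degenerate cases, and the worked 5-subject example", {
  # perfect separation
  r <- roc_curve(c(0, 0, 16, 16, 16), c(1, 1, 0, 0, 0))
  expect_equal(r$auc, 1.0)
  # uninformative: all scores identical
  r0 <- roc_curve(rep(7, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(r0$auc, 0.5)
  # worked example: all 6 case-control pairs ordered correctly
  r5 <- roc_curve(c(2, 4, 9, 11, 13), c(1, 1, 1, 0, 0))
  expect_equal(r5$auc, 1.0)
  expect_equal(r5$auc, mw_auc(c(2, 4, 9, 11, 13), c(1, 1, 1, 0, 0)))
  # perturbed to contain a tie: one half-credit pair
  s <- c(2, 4, 11, 11, 13); l <- c(1, 1, 1, 0, 0)
  expect_equal(roc_curve(s, l)$auc, mw_auc(s, l))
  expect_equal(roc_curve(s, l)$auc, (6 - 0.5) / 6)
  expect_error(roc_curve(c(1, 2, 3), c(1, 1, 1)), "at least one")
})

test_that("ROC points are monotone and span (0,0) to (1,1)", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    s <- sample(0:16, n, replace = TRUE)
    l <- c(1, 0, rbinom(n - 2, 1, 0.5))
    r <- roc_curve(s, l)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(unlist(r$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points), c("fpr", "tpr")]),
                 c(fpr = 1, tpr = 1))
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  }
})

test_that("trapezoid AUC equals brute-force Mann-Whitney on 200 random cohorts", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    scores <- sample(0:16, n, replace = TRUE)
    labels <- c(1, 0, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    expect_equal(roc_curve(scores, labels)$auc, mw_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil CI brackets the AUC and stays in [0,1]", {
  set.seed(8)
  s <- c(rnorm(40, 5, 2), rnorm(40, 10, 2))
  s <- pmin(pmax(round(s), 0), 16)
  r <- roc_curve(s, rep(c(1, 0), each = 40))
  expect_lte(r$auc_ci[1], r$auc)
  expect_gte(r$auc_ci[2], r$auc)
  expect_gte(r$auc_ci[1], 0); expect_lte(r$auc_ci[2], 1)
})

test_that("Youden-optimal cutoff matches exhaustive search, ties broken low", {
  # perfect separation: unique separating threshold
  r <- roc_curve(c(0, 1, 12, 14), c(1, 1, 0, 0))
  oc <- optimal_cutoff(r)
  expect_equal(oc$J, 1)
  expect_equal(oc$threshold, 2)   # lowest t with all cases < t <= all controls
  # flat curve: J = 0 everywhere, lowest threshold wins
  rf <- roc_curve(rep(5, 4), c(1, 1, 0, 0))
  expect_equal(optimal_cutoff(rf)$J, 0)
  expect_equal(optimal_cutoff(rf)$threshold, min(rf$thresholds))
  expect_equal(optimal_cutoff(rf)$criterion, "youden")
  # exhaustive enumeration oracle on the worked 5-subject example
  s <- c(2, 4, 9, 11, 13); l <- c(1, 1, 1, 0, 0)
  r5 <- roc_curve(s, l)
  J_by_t <- vapply(r5$thresholds, function(t) {
    sum(s < t & l == 1) / sum(l) - sum(s < t & l == 0) / sum(!l)
  }, numeric(1))
  best <- min(r5$thresholds[J_by_t == max(J_by_t)])
  expect_equal(optimal_cutoff(r5)$threshold, best)
})

test_that("pearson_r matches the closed form and validates input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  y <- c(2.0, 1.5, 4.0, 3.0, 6.0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_hand)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "length")
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
})

test_that("build_2x2 pools groups from fixtures and cohorts", {
  t1 <- fixtures_table1()
  tab <- build_2x2(t1, "needs_assistance_money_meds")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(309L, 338L, 9L, 157L))
  tab2 <- build_2x2(t1, "head_trauma_loc")
  expect_equal(c(tab2$a, tab2$b, tab2$c, tab2$d), c(57L, 590L, 6L, 160L))
  expect_error(build_2x2(t1, "nope"), "unknown factor")
  expect_error(build_2x2(t1, "stroke", impaired_groups = "martian"),
               "unknown group")
  # cohort path: factor absent everywhere gives a = c = 0
  coh <- random_cohort(20, 3)
  coh$stroke <- 0
  tab3 <- build_2x2(coh, "stroke")
  expect_equal(c(tab3$a, tab3$c), c(0L, 0L))
  expect_equal(tab3$b + tab3$a, sum(coh$group %in% c("mci", "dementia")))
})
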