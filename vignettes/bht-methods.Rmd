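---
title: "The Brain Health Test: scoring rules, validation statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Brain Health Test: scoring rules, validation statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bht)
```

## The screening problem

Dementia is widely under-recognized in primary care, where physicians
have neither the time nor the training for a full neuropsychological
work-up. A pragmatic answer is *two-stage opportunistic screening*
during routine health checks: first identify subjects at elevated risk
from information that is already available (age, comorbidities, memory
complaints), then give only that subset a brief objective cognitive
test. The Brain Health Test (BHT) is such an instrument, developed for
the Taiwanese primary-care setting and validated on a memory-clinic
cohort of 813 subjects aged 50 or older (166 cognitively healthy, 225
with mild cognitive impairment, 422 with dementia). This package
implements the instrument's deterministic scoring rules, the closed-form
statistics used to validate it, and a simulator that emulates the
development cohort.

## Stage 1: the risk score and triage rule

The risk score (RS) is a weighted sum: age decade bins (50–59 → 0 up to
≥90 → 4, both edges inclusive, fractional ages floored since ages are
recorded in whole years), sex (male 1, female 2), one point each for six
ordinary risk factors (BMI < 18, under six years of education, stroke,
diabetes, hypertension, hyperlipidemia), and three points each for the
two factors with large observed odds ratios (head trauma with
consciousness change, and two-week depressed mood/anhedonia). The
maximum is 18.

Two deliberate quirks are preserved rather than "fixed":

* the sex weights come verbatim from the instrument's weight table, so
  the *minimum* RS is 1 (a 50-year-old man with no factors), not 0;
* BMI enters as a precomputed strict-inequality flag (`bmi_lt18`);
  `bmi_flag()` offers the same strict `< 18` rule for numeric BMI.

A subject is triaged *high-risk* when any of three criteria holds:
subjective memory decline (subject **or** informant report), needing
help to manage money or medications, or RS ≥ 8. Memory impairment
noticed by medical staff is carried in the data model — the instrument
records it — but does not trigger triage: the triage rule names only the
subject/informant reports and the assistance criterion, and we follow
that literal wording. This was a genuinely open reading; the choice is
recorded here and in the data model's documentation.

## Stage 2: the 16-point cognitive test

BHT-cog sums orientation to time (0–4), immediate recall of five items
(0–5), a categorical verbal fluency task binned to 0–2 points (fewer
than 5 four-legged animals in one minute → 0, 5–8 → 1, 9 or more → 2;
the bin edges are the healthy and dementia group means of the raw
count), and delayed recall (0–5). The Clock Drawing Test was piloted for
the instrument but dropped because 39% of participants — including 60%
of low-education healthy subjects — could not complete it; this package
therefore never scores it. At the published operating cutoff of 10, a
score **below** 10 is screen-positive, 10 or above is negative.

### The combined rule

The development study reports combined RS + BHT-cog performance without
operationalizing "combined". We implement it as the *sequential
conjunction* that mirrors the instrument's stated workflow: the triage
gate decides who takes the cognitive test, and a subject is positive iff
high-risk **and** cog < cutoff. This reading has a checkable structural
consequence — the two-stage positive set is a subset of the cog-only
positive set, so specificity can only rise and sensitivity only fall
relative to the cognitive test alone — which the test suite asserts on
random cohorts, and which matches the direction of the published
combined-rule numbers (specificity 87.3% → 92.2%, sensitivity 91.5% →
90.8%).

## Validation statistics

* **Confusion metrics.** sens = TP/(TP+FN), spec = TN/(TN+FP),
  PPV = TP/(TP+FP), NPV = TN/(TN+FN). A zero denominator yields `NA`
  plus an explicit `undefined` flag, never a silent 0.
* **Odds ratios.** OR = ad/bc with the Woolf (logit) interval
  $\exp(\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$. The
  Woolf interval was chosen because it exactly reproduces all four
  published CI pairs from the published group counts (24.3 [15.2–38.7],
  15.9 [8.0–31.8], 2.6 [1.1–6.1], 3.4 [1.9–6.0]); the study does not
  name its method. Zero cells take the Haldane–Anscombe +0.5 on every
  cell, flagged in the result.
* **ROC/AUC.** Integer scores are swept over every threshold with the
  positive-low convention (positive iff score < t), giving a curve from
  (0,0) to (1,1); the trapezoidal area equals the tie-corrected
  Mann–Whitney probability P(case < control) + ½P(tie). The test suite
  keeps a brute-force pair-counting oracle and checks the identity on
  200 random cohorts. The AUC interval is Hanley–McNeil — approximate,
  documented as such, and not an acceptance surface.
* **Optimal cutoff.** Youden's J = sens + spec − 1, ties broken toward
  the lower threshold (the more specific operating point under the
  positive-low convention).
* **Rounding.** Internal values keep full precision; published-style
  presentation rounds half-up to one decimal (`round_half_up()`),
  because R's banker's rounding would turn e.g. 0.25 into 0.2.

Group-difference hypothesis tests used in the development study (ANOVA,
Tukey post-hoc, multivariate GLM) are off-the-shelf procedures, not part
of the instrument, and are intentionally out of scope.

### Known inconsistencies in the published summary numbers

The packaged fixtures encode the published per-group counts with two
documented resolutions:

* the healthy-group hypertension count is printed as "930 (56%)",
  impossible for n = 166; it is encoded as 93 (93/166 = 56.0%);
* the printed triage specificity "44%" conflicts with the printed
  counts (77 low-risk healthy of 166 = 46.4%); the package reproduces
  the count-derived 46.4% and treats only the sensitivity 98.1%
  (635/647) as a reproduction target;
* the assistance-need odds ratio is printed both as 15.9 (which the
  group counts reproduce) and 14.4 (derivation unstated); the package
  reports 15.9.

## The synthetic cohort generator

`default_config()` is the stated world of the development cohort: group
sizes 166/225/422; per-group age means/SDs (72.3±8.4, 73.3±8.7,
79.0±8.4, truncated below at 50); female fractions; the per-group
prevalence of each of the twelve risk-factor/complaint flags; and
per-item cognitive means/SDs (e.g. fluency 9.5±3.3 healthy vs 4.7±3.2
dementia). Fluency counts are clipped to 0–30 — about six SDs above the
healthy mean, wide enough never to bind in practice.

Items are generated as *rounded, clipped normals*: only means and SDs
are published, so no discrete distribution can be fitted. Consequences
to keep in mind when interpreting a green test:

* clipping at the range ends shifts group means slightly (the suite
  allows ±0.5 against the published BHT-cog group totals of
  12.5/10.3/4.7);
* items are independent within group by default, which *understates*
  the variance of the total score relative to a real cohort where items
  correlate through disease severity — so the synthetic dementia-vs-
  healthy AUC (≈0.99) exceeds the real cohort's 0.958. The acceptance
  band [0.90, 1.00] asserts consistency with the published
  separability, not a reproduction of it.

The dependence structure among items is unreported, so it is exposed as
a `coupling` parameter in [0,1] rather than guessed: each subject draws
one latent severity $z \sim N(0,1)$ and item values are
$\mu + \sigma(\rho z + \sqrt{1-\rho^2}\,\varepsilon)$. The default is
$\rho = 0$. Similarly, the published group RS means (6.6/6.9/8.1) are
*not* calibration targets: they are not reproducible from the published
marginal prevalences under independence, which implies a correlation
structure among risk factors that the study does not report.

Determinism: `simulate_cohort(config, seed)` is a pure function of its
arguments, restores the caller's RNG state, and its output always
passes cohort validation with zero exclusions.

## Cohort I/O and degenerate inputs

The CSV schema fixes column names, 0/1 booleans, lower-case group
labels, and empty-string missing values. Reading is lenient by default:
invalid rows (missing fields, out-of-range items, age under 50,
duplicate subject ids) are dropped and itemized with line numbers,
mirroring the development study's exclusion of 54 incomplete subjects;
`strict = TRUE` turns the first invalid row into an error. Scalar
scoring functions, by contrast, treat missing or malformed fields as
immediate errors — a single subject scored interactively should never
be silently skipped.

Education-stratified validation sub-reports use the instrument's
<6-years split; strata with fewer than 10 subjects in either arm are
still reported but flagged unstable.

## Limitations

* The simulator emulates marginal distributions, not the joint
  dependence of risk factors and cognition; green simulator tests
  establish internal consistency of the pipeline, not clinical
  performance.
* Cohort-level reproduction of the published AUC 0.958, sens/spec
  91.5%/87.3% and the MMSE correlation 0.821 requires the study's raw
  per-subject data and is outside the package's test surface.
* The instrument screens; it does not diagnose, stage, or subtype
  dementia.
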