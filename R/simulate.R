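#' Synthetic three-group cohort simulation
#'
#' Seedable generator of synthetic memory-clinic cohorts calibrated to the
#' published per-group distributions of the development study: ages from
#' truncated normals (lower bound 50, the inclusion criterion), risk
#' factors as per-group Bernoulli draws at the published prevalences, and
#' cognitive items as normals discretized and clipped to their scoring
#' ranges. Only means/SDs of the items are published, so clipped-rounded
#' normals are an approximation, not a fit.
#'
#' An optional latent-severity `coupling` in \[0,1\] makes all four item
#' scores of a subject co-vary through one shared standard-normal latent
#' variable (0 = items independent given group, the default; the
#' dependence structure of the real cohort is unreported, so it is exposed
#' as a knob rather than guessed).
#'
#' @name bht-simulate
NULL

#' Default simulation configuration
#'
#' Populated verbatim from the published group characteristics: group
#' sizes 166/225/422 (healthy/MCI/dementia), per-group age mean/SD, female
#' fraction, risk-factor prevalences, and per-item cognitive score
#' means/SDs. Memory-complaint and assistance-need flags use the published
#' per-group prevalences of those complaints.
#'
#' @param coupling latent-severity coupling in \[0,1\], default 0.
#' @return an object of class `sim_config`.
#' @export
default_config <- function(coupling = 0) {
  t1 <- fixtures_table1()
  items <- fixtures_item_stats()
  stopifnot(coupling >= 0, coupling <= 1)
  structure(list(
    groups = names(t1$n),
    n = t1$n,
    age = t1$age,
    female_frac = t1$factor_pct["female", ],
    prevalence = t1$factor_pct[setdiff(rownames(t1$factor_pct),
                                       c("female", "memory_decline_any")), ],
    items = items,
    item_range = list(orientation_time = c(0L, 4L),
                      immediate_recall = c(0L, 5L),
                      fluency_count = c(0L, 30L),
                      delayed_recall = c(0L, 5L)),
    coupling = coupling
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("simulation config:",
      paste(sprintf("%s n=%d", x$groups, x$n), collapse = ", "),
      sprintf("| coupling %.2f\n", x$coupling))
  invisible(x)
}

#' Read / write a simulation configuration as JSON
#'
#' @param path JSON file path.
#' @return for `read_sim_config`, a `sim_config`; for `write_sim_config`,
#'   `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- default_config()
  nv <- function(x) stats::setNames(as.numeric(unlist(x)), names(unlist(x)))
  if (!is.null(raw$n)) cfg$n <- stats::setNames(as.integer(unlist(raw$n)),
                                                names(unlist(raw$n)))
  if (!is.null(raw$coupling)) cfg$coupling <- as.numeric(raw$coupling)
  if (!is.null(raw$age)) cfg$age <- list(mean = nv(raw$age$mean),
                                         sd = nv(raw$age$sd))
  if (!is.null(raw$female_frac)) cfg$female_frac <- nv(raw$female_frac)
  if (!is.null(raw$prevalence)) {
    pf <- as.data.frame(raw$prevalence)
    if (!"factor" %in% names(pf)) {
      stop("config prevalence table needs a 'factor' column", call. = FALSE)
    }
    m <- as.matrix(pf[, setdiff(names(pf), "factor"), drop = FALSE])
    rownames(m) <- pf$factor
    cfg$prevalence <- m
  }
  validate_sim_config(cfg)
  cfg
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  prev <- as.data.frame(obj$prevalence)
  prev <- cbind(factor = rownames(obj$prevalence), prev)
  obj$prevalence <- prev
  obj <- listify_named(obj)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$n < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (any(config$prevalence < 0 | config$prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (any(unlist(lapply(config$items, `[[`, "sd")) <= 0) ||
      any(config$age$sd <= 0)) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  if (config$coupling < 0 || config$coupling > 1) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  invisible(config)
}

# normal truncated below at `lo`, via inverse-CDF
.rtruncnorm_lower <- function(n, mean, sd, lo) {
  p_lo <- stats::pnorm(lo, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

#' Simulate a synthetic cohort
#'
#' Draws a full per-subject cohort from a [default_config()]-style
#' configuration. Identical `(config, seed)` pairs give identical cohorts.
#' Ages are truncated normals rounded to whole years; each risk factor is
#' an independent Bernoulli at its group prevalence; each cognitive item
#' is a normal draw (shifted jointly by the latent severity when
#' `coupling > 0`), rounded and clipped to its scoring range. All
#' generated records satisfy the cohort schema, so they round-trip through
#' [write_cohort()] / [read_cohort()] with zero exclusions.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; every source of randomness derives from it.
#' @return a cohort data.frame of `sum(config$n)` rows.
#' @export
simulate_cohort <- function(config = default_config(), seed = 1L) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  out <- lapply(config$groups, function(g) {
    n <- config$n[[g]]
    age <- as.integer(round(.rtruncnorm_lower(n, config$age$mean[[g]],
                                              config$age$sd[[g]], 50)))
    age <- pmax(age, 50L)
    sex <- ifelse(stats::runif(n) < config$female_frac[[g]],
                  "female", "male")
    df <- data.frame(
      subject_id = sprintf("%s_%04d", g, seq_len(n)),
      group = g, age = age, sex = sex,
      stringsAsFactors = FALSE
    )
    for (f in rownames(config$prevalence)) {
      df[[f]] <- as.integer(stats::runif(n) < config$prevalence[f, g])
    }
    z <- stats::rnorm(n)  # shared latent severity (lower = worse)
    rho <- config$coupling
    for (it in names(config$items)) {
      mu <- config$items[[it]]$mean[[g]]
      sd <- config$items[[it]]$sd[[g]]
      eps <- stats::rnorm(n)
      val <- mu + sd * (rho * z + sqrt(1 - rho^2) * eps)
      rng <- config$item_range[[it]]
      df[[it]] <- as.integer(pmin(pmax(round(val), rng[1]), rng[2]))
    }
    df
  })
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  # schema column order
  cohort[, cohort_columns()$required]
}
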