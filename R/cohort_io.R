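#' Cohort CSV input/output and validation
#'
#' A cohort is a plain `data.frame`, one row per subject, in a fixed CSV
#' schema: UTF-8, comma-separated, mandatory header, booleans encoded 0/1,
#' missing values as empty strings, group labels lower-case. See
#' [cohort_columns()] for the column list.
#'
#' @name bht-cohort-io
NULL

.flag_cols <- c("education_lt6", "bmi_lt18", "stroke", "diabetes",
                "hypertension", "hyperlipidemia", "head_trauma_loc",
                "depression", "memory_decline_subject",
                "memory_decline_informant", "memory_impairment_doctor",
                "needs_assistance_money_meds")

.item_cols <- c("orientation_time", "immediate_recall", "fluency_count",
                "delayed_recall")

.item_max <- c(orientation_time = 4L, immediate_recall = 5L,
               fluency_count = NA_integer_, delayed_recall = 5L)

#' Cohort CSV column names
#'
#' @return a list with `required` and `optional` column-name vectors.
#' @export
cohort_columns <- function() {
  list(
    required = c("subject_id", "group", "age", "sex", .flag_cols, .item_cols),
    optional = c("mmse", "cdr")
  )
}

# per-row validation; returns character vector of problems (empty if valid)
.validate_record <- function(row) {
  bad <- character(0)
  if (is.na(row$subject_id) || !nzchar(row$subject_id)) {
    bad <- c(bad, "missing subject_id")
  }
  if (is.na(row$group) || !row$group %in% c("healthy", "mci", "dementia",
                                            "unknown")) {
    bad <- c(bad, "invalid group")
  }
  if (is.na(row$age) || row$age != trunc(row$age) || row$age < 50) {
    bad <- c(bad, "age missing or < 50")
  }
  if (is.na(row$sex) || !row$sex %in% c("male", "female")) {
    bad <- c(bad, "invalid sex")
  }
  for (f in .flag_cols) {
    v <- row[[f]]
    if (is.na(v) || !v %in% c(0, 1)) bad <- c(bad, paste0("invalid ", f))
  }
  for (it in .item_cols) {
    v <- row[[it]]
    hi <- .item_max[[it]]
    if (is.na(v) || v != trunc(v) || v < 0 || (!is.na(hi) && v > hi)) {
      bad <- c(bad, paste0("invalid ", it))
    }
  }
  if (!is.na(row$mmse) && (row$mmse < 0 || row$mmse > 30)) {
    bad <- c(bad, "invalid mmse")
  }
  if (!is.na(row$cdr) && !row$cdr %in% c(0, 0.5, 1, 2, 3)) {
    bad <- c(bad, "invalid cdr")
  }
  bad
}

#' Read a cohort CSV with validation
#'
#' Reads per-subject records and validates every row against the schema.
#' In lenient mode (default) invalid or incomplete rows are dropped and
#' reported — mirroring the development study's exclusion of subjects with
#' incomplete data — while in strict mode the first invalid row is an
#' error naming its line number.
#'
#' @param path path to a cohort CSV file.
#' @param strict if `TRUE`, fail on the first invalid row instead of
#'   excluding it.
#' @return a list of class `cohort_read`: `cohort` (data.frame of valid
#'   records), `excluded` (data.frame with `line`, `subject_id`,
#'   `reason`), `n_input`, `n_excluded`.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = c(subject_id = "character"))
  req <- cohort_columns()$required
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("malformed header, missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in cohort_columns()$optional) {
    if (!opt %in% names(df)) df[[opt]] <- rep(NA_real_, nrow(df))
  }
  if (nrow(df) == 0) {
    return(structure(list(cohort = df,
                          excluded = data.frame(line = integer(0),
                                                subject_id = character(0),
                                                reason = character(0)),
                          n_input = 0L, n_excluded = 0L),
                     class = "cohort_read"))
  }
  df$group <- tolower(df$group)
  df$sex <- tolower(df$sex)

  reasons <- vapply(seq_len(nrow(df)), function(i) {
    paste(.validate_record(df[i, ]), collapse = "; ")
  }, character(1))
  dup <- duplicated(df$subject_id) & nzchar(df$subject_id) &
    !is.na(df$subject_id)
  reasons[dup] <- trimws(paste(reasons[dup], "duplicate subject_id",
                               sep = "; "), whitespace = ";[ ]*")
  bad <- nzchar(reasons)
  if (strict && any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid record at line %d: %s", i + 1L, reasons[i]),
         call. = FALSE)
  }
  excluded <- data.frame(line = which(bad) + 1L,
                         subject_id = df$subject_id[bad],
                         reason = reasons[bad],
                         stringsAsFactors = FALSE)
  cohort <- df[!bad, , drop = FALSE]
  rownames(cohort) <- NULL
  for (f in c(.flag_cols, .item_cols, "age")) {
    cohort[[f]] <- as.integer(cohort[[f]])
  }
  structure(list(cohort = cohort, excluded = excluded,
                 n_input = nrow(df), n_excluded = sum(bad)),
            class = "cohort_read")
}

#' @export
print.cohort_read <- function(x, ...) {
  cat(sprintf("cohort: %d valid record(s), %d excluded of %d input row(s)\n",
              nrow(x$cohort), x$n_excluded, x$n_input))
  if (x$n_excluded > 0) {
    cat("excluded lines:", paste(x$excluded$line, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: booleans 0/1, missing as empty string,
#' columns in schema order.
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- cohort_columns()
  keep <- c(cols$required, intersect(cols$optional, names(cohort)))
  utils::write.csv(cohort[, keep, drop = FALSE], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Summarize a cohort, Table-1 style
#'
#' Per-group sizes, risk-factor counts and percentages (including the
#' derived `memory_decline_any` pooled complaint and `female`), raw
#' cognitive item means/SDs, and BHT-cog total means/SDs. SDs are sample
#' standard deviations (n - 1). Groups with no subjects are omitted with a
#' warning.
#'
#' @param cohort a cohort data.frame with a `group` column.
#' @return a `cohort_summary` (same shape as [fixtures_table1()], plus
#'   `item_stats` and `cog_totals`).
#' @export
summarize_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  all_groups <- c("healthy", "mci", "dementia", "unknown")
  present <- intersect(all_groups, unique(cohort$group))
  absent <- setdiff(intersect(all_groups[1:3], all_groups), present)
  if (length(setdiff(all_groups[1:3], present))) {
    warning("group(s) with no subjects omitted: ",
            paste(setdiff(all_groups[1:3], present), collapse = ", "),
            call. = FALSE)
  }
  n <- vapply(present, function(g) sum(cohort$group == g), integer(1))

  factor_rows <- c(.flag_cols, "memory_decline_any", "female")
  counts <- matrix(0L, length(factor_rows), length(present),
                   dimnames = list(factor_rows, present))
  cog <- bht_cog_score_vec(cohort)
  item_stats <- list()
  cog_totals <- list(mean = stats::setNames(numeric(length(present)), present),
                     sd = stats::setNames(numeric(length(present)), present))
  for (g in present) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    for (f in .flag_cols) counts[f, g] <- sum(sub[[f]])
    counts["memory_decline_any", g] <-
      sum(sub$memory_decline_subject | sub$memory_decline_informant)
    counts["female", g] <- sum(sub$sex == "female")
    cog_totals$mean[g] <- mean(cog[cohort$group == g])
    cog_totals$sd[g] <- stats::sd(cog[cohort$group == g])
  }
  for (it in .item_cols) {
    item_stats[[it]] <- list(
      mean = vapply(present, function(g) mean(cohort[[it]][cohort$group == g]),
                    numeric(1)),
      sd = vapply(present, function(g) stats::sd(cohort[[it]][cohort$group == g]),
                  numeric(1))
    )
  }
  structure(list(
    n = n,
    factor_counts = counts,
    factor_pct = sweep(counts, 2, n, "/"),
    item_stats = item_stats,
    cog_totals = cog_totals
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort summary\n  group sizes:",
      paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "), "\n")
  if (!is.null(x$cog_totals)) {
    cat("  BHT-cog mean (sd):",
        paste(sprintf("%s %.1f (%.1f)", names(x$cog_totals$mean),
                      x$cog_totals$mean, x$cog_totals$sd), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Export a cohort summary as JSON
#'
#' @param summary a `cohort_summary`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  obj <- unclass(summary)
  obj$factor_counts <- as.data.frame(obj$factor_counts)
  obj$factor_pct <- as.data.frame(obj$factor_pct)
  obj <- listify_named(obj)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
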