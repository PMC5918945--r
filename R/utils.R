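#' Round half up to a fixed number of decimals
#'
#' Presentation-layer rounding used throughout the package: exact halves go
#' away from zero (so 0.15 -> 0.2 at one decimal), unlike [base::round()],
#' which rounds half to even. Internal computations always keep full
#' precision; this is applied only when a value is reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.25, 1)   # 0.3
#' round_half_up(98.145, 1) # 98.1
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage on the printed scale (e.g. 98.1), half-up at one decimal
fmt_pct <- function(p, digits = 1) round_half_up(100 * p, digits)

# strict scalar checks -------------------------------------------------------

is_flag <- function(x) {
  (is.logical(x) && length(x) == 1L && !is.na(x)) ||
    (is.numeric(x) && length(x) == 1L && !is.na(x) && x %in% c(0, 1))
}

as_flag <- function(x, name = deparse(substitute(x))) {
  if (!is_flag(x)) {
    stop(sprintf("'%s' must be a single non-missing 0/1 or TRUE/FALSE value",
                 name), call. = FALSE)
  }
  as.logical(x)
}

# recursively turn named atomic vectors into lists so jsonlite keeps names
listify_named <- function(x) {
  if (is.data.frame(x)) {
    x
  } else if (is.list(x)) {
    lapply(x, listify_named)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else {
    x
  }
}

check_int_range <- function(x, lo, hi, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x)) {
    stop(sprintf("'%s' must be a single non-missing integer", name),
         call. = FALSE)
  }
  if (x < lo || (is.finite(hi) && x > hi)) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lo,
                 if (is.finite(hi)) hi else "Inf", x), call. = FALSE)
  }
  as.integer(x)
}
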