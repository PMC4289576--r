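#' Round half away from zero
#'
#' Printed percentages in screening reports conventionally round 0.5 away
#' from zero (so 9.45 -> 9.5), unlike [base::round()] which rounds half to
#' even. All percentage formatting in this package goes through this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(c(0.05, 0.15, -0.25), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded to one decimal
#'
#' @param cases numerator count.
#' @param n denominator count.
#' @param digits decimals (default 1).
#' @return percentage on the 0-100 scale; `NA` when `n` is zero.
#' @export
pct <- function(cases, n, digits = 1) {
  x <- 100 * cases / n
  out <- round_half_up(x, digits)
  out[!is.finite(x)] <- NA_real_
  out
}

#' Format a "cases/n (%)" cell
#'
#' Mirrors the cases/n (percent) layout used in epidemiological prevalence
#' tables.
#'
#' @param cases numerator count.
#' @param n denominator count.
#' @return character vector like `"588/1638 (35.9)"`; `"0/0 (NA)"` when the
#'   denominator is empty.
#' @export
fmt_cases <- function(cases, n) {
  sprintf("%d/%d (%s)", cases, n, ifelse(n > 0, sprintf("%.1f", pct(cases, n)), "NA"))
}

# stop() with a consistent prefix and no call noise
fa_stop <- function(...) stop(..., call. = FALSE)

# require columns in a data.frame, error listing the missing ones
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    fa_stop(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
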