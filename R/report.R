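#' Half-up rounding at a fixed number of decimals
#'
#' Rounds `x` to `digits` decimal places with ties going away from zero
#' (commercial/"half-up" rounding), the convention used for every percentage
#' and ratio this package prints. This differs from base [round()], which
#' rounds half to even.
#'
#' A small relative guard absorbs binary floating-point representation error
#' so that quantities that are exactly on a half in rational arithmetic
#' (e.g. `83/96 * 100` at one decimal) round up as intended.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (may be 0).
#' @return numeric vector of `length(x)`.
#' @examples
#' round_half_up(2.5, 0)     # 3, not 2
#' round_half_up(86.458, 1)  # 86.5
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  z <- x * p
  guard <- pmax(abs(z), 1) * 1e-10
  sign(z) * floor(abs(z) + 0.5 + guard) / p
}

#' Construct a reported value
#'
#' A `report_value` carries a full-precision raw number alongside its
#' half-up rounded form at a declared precision, so rounded display values
#' never replace the underlying quantity in downstream arithmetic.
#'
#' @param raw numeric scalar, full precision.
#' @param digits number of decimals for the rounded form.
#' @param units character label (e.g. `"%"`, `"SSRs/kb"`).
#' @return an object of class `report_value` (a list with `raw`, `rounded`,
#'   `digits`, `units`).
#' @seealso [report_percentage()]
#' @export
report_value <- function(raw, digits = 2, units = "") {
  stopifnot(is.numeric(raw), length(raw) == 1L, is.finite(raw))
  structure(
    list(raw = raw, rounded = round_half_up(raw, digits),
         digits = as.integer(digits), units = units),
    class = "report_value"
  )
}

#' @export
print.report_value <- function(x, ...) {
  cat(formatC(x$rounded, format = "f", digits = x$digits),
      if (nzchar(x$units)) x$units else "", "\n")
  invisible(x)
}

#' @export
format.report_value <- function(x, ...) {
  paste0(formatC(x$rounded, format = "f", digits = x$digits),
         if (nzchar(x$units)) paste0(" ", x$units) else "")
}

#' Report a percentage at a declared precision
#'
#' `100 * numerator / denominator`, half-up rounded.
#'
#' @param numerator,denominator numeric scalars; `denominator` must be > 0.
#' @param digits decimals in the rounded form (default 2).
#' @return a [report_value()] with units `"%"`.
#' @examples
#' report_percentage(917770, 13167418)  # 6.97 %
#' report_percentage(83, 96, digits = 1)  # 86.5 %
#' @export
report_percentage <- function(numerator, denominator, digits = 2) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            length(numerator) == 1L, length(denominator) == 1L)
  if (!is.finite(denominator) || denominator <= 0) {
    abort("`denominator` must be a positive finite number.")
  }
  report_value(100 * numerator / denominator, digits = digits, units = "%")
}
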