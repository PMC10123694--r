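#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (half-up for positive
#' values), as used wherever a summary value is reported at printed
#' precision. Base [round()] rounds half to even, which disagrees with the
#' convention of printed tables for values ending in 5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the reporting
#'   precision used throughout).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(2.345)   # 2.35
#' round_half_up(-2.345)  # -2.35
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop unless all values are finite numerics
assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric, got non-finite value(s)", name),
         call. = FALSE)
  }
  invisible(x)
}
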