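#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used on all reported dollar and percent
#' figures. R's `round()` rounds half to even, which disagrees with published
#' financial tables on exact .5 cases.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(2337.5)   # 2338, where round() gives 2338 but round(0.5) gives 0
#' round_half_up(-58.5)    # -59
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Round to whole dollars
#'
#' Reporting-boundary rounding: internal arithmetic is kept at full precision
#' and collapsed to integer dollars only when a table cell is produced.
#'
#' @param x numeric vector of dollar amounts.
#' @return integer-valued numeric vector.
#' @export
round_dollar <- function(x) round_half_up(x, 0)

# stop() with the caller's argument name in the message
assert_nonneg <- function(x, what = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", what), call. = FALSE)
  }
  invisible(x)
}

assert_scalar_prob <- function(x, what = deparse(substitute(x))) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
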