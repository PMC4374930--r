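#' Round half away from zero
#'
#' Conventional decimal rounding (0.5 rounds up in magnitude), as used when
#' comparing computed quantities against values printed at a fixed decimal
#' precision; base R's [round()] rounds half to even.
#'
#' @param x numeric.
#' @param digits decimal places (may be negative).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
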