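#' Round half away from zero
#'
#' Presentation rounding used for percent metrics and Youden indices:
#' exact halves round away from zero (so 0.005 -> 0.01), unlike
#' [base::round()]'s round-half-even. Applied only when formatting
#' reports; internal computation is never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5) / p
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## is a scalar present (non-NULL, non-NA)?
is_present <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)

stop_ts <- function(...) stop(..., call. = FALSE)
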