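#' Round half away from zero
#'
#' Display rounding used in reports: exact halves round up in magnitude
#' (7.475 -> 7.48), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop with a consistent prefix
rc_stop <- function(...) stop(..., call. = FALSE)

rc_warn <- function(...) warning(..., call. = FALSE)

# check a single non-missing finite number
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
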