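`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Reporting-layer rounding used for printed percent helicities and table
#' values: halves round away from zero (so 6.5 -> 7, -6.5 -> -7), unlike
#' [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# gas constant, J mol^-1 K^-1
.R_GAS <- 8.314

# cal <-> J
.CAL_J <- 4.184
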