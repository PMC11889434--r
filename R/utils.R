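#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.005 -> 0.01), matching how disproportionality results are
#' conventionally printed. `base::round()` uses round-half-even, which
#' disagrees on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(2.085, 0.575), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() without the call, keeping messages clean for CLI users
abort_config <- function(...) stop(..., call. = FALSE)
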