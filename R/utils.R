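#' Round half away from zero
#'
#' Percentages in reports follow the common "round half up" convention
#' (round-half-away-from-zero), not R's banker's rounding.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the generators flows from one master seed through
#' named streams, so that adding a component never perturbs the draws of
#' another. The derived seed stays below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param stream character stream name
#' @return integer seed for the named stream
#' @export
streamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 17) %% 2147483629)
}

# internal: stop with a prefixed message
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# internal: check scalar probability-like value
.checkProb <- function(x, name, lo = 0, hi = 1, lo.open = FALSE) {
  ok <- is.numeric(x) && all(x <= hi) &&
    (if (lo.open) all(x > lo) else all(x >= lo))
  if (!ok) .fail("%s must lie in %s%g, %g]", name,
                 if (lo.open) "(" else "[", lo, hi)
  invisible(TRUE)
}
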