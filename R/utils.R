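# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half up at a fixed number of decimals
#'
#' Presentation rounding used throughout the package: ratios are kept at full
#' precision internally and rounded only for display, with halves rounded away
#' from zero (so 18.65 -> 18.7), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return Rounded numeric vector; `NA` passes through.
#' @export
#' @examples
#' round_half_up(c(27.146, 12.85), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  out <- sign(x) * floor(abs(x) * m + 0.5) / m
  out[is.na(x)] <- NA_real_
  out
}

# Shortest decimal string that parses back to the identical double.
# Used by the CSV writer so that read(write(x)) is bit-exact.
fmt_roundtrip <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

is_true <- function(x) !is.na(x) & x

stop_mnm <- function(fmt, ..., class = "mnm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
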