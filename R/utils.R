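#' Percentage with half-up rounding
#'
#' All "n (%)" figures in the package's reports are computed by this one
#' function so a single rounding convention applies throughout: multiply by
#' 100 and round half-up to `decimals` decimal places.
#'
#' @param numerator Non-negative count.
#' @param denominator Positive count.
#' @param decimals Number of decimal places (default 2).
#' @return Numeric percentage.
#' @examples
#' percent(35646, 1188202) # 3.00
#' percent(1, 3)           # 33.33
#' @export
percent <- function(numerator, denominator, decimals = 2) {
  if (length(denominator) != length(numerator) && length(denominator) != 1) {
    stop("numerator and denominator lengths differ", call. = FALSE)
  }
  if (any(denominator <= 0)) {
    stop("percent(): denominator must be > 0", call. = FALSE)
  }
  if (any(numerator < 0)) {
    stop("percent(): numerator must be >= 0", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, decimals)
}

# Round half away from zero at `decimals` places. base::round() rounds half
# to even, which does not match the convention used for the package's
# reported rates. A small epsilon guards against representation error in
# values that are exactly representable at the target precision.
round_half_up <- function(x, decimals = 2) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# A value is missing when absent (NA) or textually empty/whitespace-only.
# The literal category "Unknown" is a recorded value, hence present.
is_missing_value <- function(x) {
  if (is.character(x)) {
    is.na(x) | !nzchar(trimws(x))
  } else {
    is.na(x)
  }
}

# Escape a literal string for use inside a PCRE pattern.
regex_escape <- function(x) {
  gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)
}

# Central 99% binomial interval for the observed proportion of successes in
# n trials at success probability p (normal approximation with continuity
# handled by the exact qbinom quantiles).
binom_interval99 <- function(p, n) {
  c(
    lower = stats::qbinom(0.005, n, p) / n,
    upper = stats::qbinom(0.995, n, p) / n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
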