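#' Round half away from zero
#'
#' Reporting convention used throughout the package: ties round away from
#' zero (so 0.05 -> 0.1 and -0.05 -> -0.1), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with one-decimal reporting
#'
#' Computes `100 * numerator / denominator` rounded half away from zero to
#' one decimal, the convention used for all reported fractions (e.g.
#' 3515/5765 -> 61.0).
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return percentage rounded to one decimal.
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("undefined percentage: denominator must be positive")
  }
  round_half_up(100 * numerator / denominator, 1)
}

# internal: validate an uppercase DNA string
assert_dna <- function(x, what, allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("%s must be a single non-empty DNA string", what))
  }
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, x)) {
    stop(sprintf(
      "%s contains characters outside {A,C,G,T%s} (sequences must be uppercase)",
      what, if (allow_n) ",N" else ""
    ))
  }
  invisible(x)
}

# internal: standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
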