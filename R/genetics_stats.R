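#' Segregation-ratio chi-squared test
#'
#' Goodness-of-fit chi-squared test of observed class counts against an
#' expected Mendelian ratio, as used for complementation analysis: a
#' recessive-by-recessive allelism cross scores mutant vs wild-type F1
#' against 1:1 (mutant x heterozygote) or 1:3 (heterozygote self). No
#' continuity correction is applied: with Yates' correction, 12 mutant of
#' 26 against 1:1 gives p ~ 0.84 instead of the uncorrected 0.69, and the
#' uncorrected statistic is the standard choice for multi-class
#' segregation ratios.
#'
#' @param observed Integer vector of class counts (length >= 2).
#' @param expected_ratio Positive weights of the same length, e.g.
#'   `c(1, 3)` for a 1:3 ratio.
#' @return A list of class `seg_chisq` with elements `chi2`, `df`,
#'   `p_value`, `observed`, `expected`.
#' @examples
#' segregation_chi_square(c(12, 14), c(1, 1))  # p ~ 0.69
#' segregation_chi_square(c(9, 27), c(1, 3))   # perfect fit, p = 1
#' @export
segregation_chi_square <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio) || length(observed) < 2)
    stop("observed and expected_ratio must have equal length >= 2")
  if (sum(observed) <= 0) stop("total observed count must be positive")
  if (any(expected_ratio <= 0)) stop("expected ratio weights must be > 0")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  expected <- sum(observed) * expected_ratio / sum(expected_ratio)
  if (any(expected == 0)) stop("expected count of zero")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "seg_chisq")
}

#' @export
print.seg_chisq <- function(x, ...) {
  cat(sprintf("Segregation chi-squared test: X2 = %.4g, df = %d, P = %.3g\n",
              x$chi2, x$df, x$p_value))
  cat("  observed:", paste(x$observed, collapse = " : "),
      "  expected:", paste(signif(x$expected, 4), collapse = " : "), "\n")
  invisible(x)
}

#' Haldane's map function
#'
#' Recombination fraction at genetic distance `d` Morgans under no
#' crossover interference: `r = (1 - exp(-2d)) / 2`. `d = Inf` (unlinked)
#' gives 0.5.
#'
#' @param d Genetic distance in Morgans (vectorized).
#' @return Recombination fraction in \[0, 0.5\].
#' @export
haldane_r <- function(d) {
  r <- (1 - exp(-2 * d)) / 2
  r[is.infinite(d)] <- 0.5
  r
}
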