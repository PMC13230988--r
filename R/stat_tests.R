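#' Hypothesis test result
#'
#' Lightweight container returned by the testing helpers. `adjusted_p` is
#' `NA` until a multiple-testing correction is applied across a family.
#'
#' @param statistic,dof,p_value,alternative,adjusted_p Fields; see value.
#' @return A list of class `test_result` with fields `statistic`, `dof`,
#'   `p_value`, `alternative` (`"less"`, `"greater"` or `"two_sided"`) and
#'   `adjusted_p`.
#' @keywords internal
test_result <- function(statistic, dof, p_value, alternative,
                        adjusted_p = NA_real_) {
  stopifnot(p_value >= 0, p_value <= 1)
  if (!is.na(adjusted_p) && adjusted_p < p_value)
    stop("adjusted p-value cannot be smaller than the raw p-value",
         call. = FALSE)
  structure(list(statistic = statistic, dof = dof, p_value = p_value,
                 alternative = alternative, adjusted_p = adjusted_p),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> t = %.4g, df = %.4g, p (%s) = %.4g",
              x$statistic, x$dof, x$alternative, x$p_value))
  if (!is.na(x$adjusted_p)) cat(sprintf(", BH-adjusted p = %.4g", x$adjusted_p))
  cat("\n")
  invisible(x)
}

#' One-sided one-sample t test
#'
#' Classical one-sample t statistic `(mean - mu0) / (sd / sqrt(n))` with
#' `n - 1` degrees of freedom and a one-sided p-value. Used for viability
#' ratios tested against 1 and mixing fractions tested against the random
#' expectation.
#'
#' Zero-variance input is degenerate and raises an error, except for the
#' symmetric case where every value equals `mu0` exactly: there the statistic
#' is 0 and the one-sided p-value is 0.5.
#'
#' @param values Numeric vector, length >= 2.
#' @param mu0 Null-hypothesis mean.
#' @param alternative `"less"` or `"greater"`.
#' @return A `test_result`.
#' @export
one_sample_t_one_sided <- function(values, mu0,
                                   alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("degenerate input: need at least 2 values for a t test",
         call. = FALSE)
  s <- stats::sd(values)
  n <- length(values)
  if (s == 0) {
    if (isTRUE(all.equal(mean(values), mu0)))
      return(test_result(0, n - 1, 0.5, alternative))
    stop("degenerate input: zero variance", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = mu0, alternative = alternative)
  test_result(unname(tt$statistic), unname(tt$parameter),
              unname(tt$p.value), alternative)
}

#' Two-sided Welch's unequal-variance t test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom, two-sided
#' p-value; the comparison used between aggregation regimes.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `test_result` with `alternative = "two_sided"`.
#' @export
welch_t_two_sided <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("degenerate input: both groups need at least 2 values",
         call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(test_result(0, length(a) + length(b) - 2, 1, "two_sided"))
    stop("degenerate input: both groups have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  test_result(unname(tt$statistic), unname(tt$parameter),
              unname(tt$p.value), "two_sided")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate correction applied across the family of treatment
#' conditions of one strain in one experiment. Output preserves input order
#' and is capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Attach BH-adjusted p-values to a family of test results
#'
#' @param tests List of `test_result` objects forming one testing family.
#' @return The list with `adjusted_p` filled in.
#' @export
adjust_family <- function(tests) {
  stopifnot(all(vapply(tests, inherits, logical(1), "test_result")))
  adj <- benjamini_hochberg(vapply(tests, function(x) x$p_value, numeric(1)))
  Map(function(x, a) { x$adjusted_p <- a; x }, tests, adj)
}
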