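#' Pearson correlation with a t-test p-value
#'
#' Thin wrapper around [stats::cor.test()] returning the sample Pearson
#' correlation and its two-sided p-value (t distribution, n - 2 df), in the
#' shape used by the pipeline reports.
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return list with elements `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_cc(c(1, 2, 3), c(1, 2, 4))
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Chi-square test on a 2x2 contingency table
#'
#' Wraps [stats::chisq.test()]; Yates continuity correction is on by default,
#' matching the convention under which the wobble-site enrichment statistic of
#' 11.59 for mutated vs all sites is obtained.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive marginals.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return object of class `chi_square_2x2`: list with `statistic`, `df`,
#'   `p_value`, `expected`, `continuity_corrected`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(72, 340, 4027, 29872), 2, 2, byrow = TRUE))
chi_square_2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all marginals must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, expected = ht$expected,
         continuity_corrected = yates),
    class = "chi_square_2x2"
  )
}

#' @export
print.chi_square_2x2 <- function(x, ...) {
  cat(sprintf("2x2 chi-square%s: X^2 = %.4g, df = %d, p = %.4g\n",
              if (x$continuity_corrected) " (Yates-corrected)" else "",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' Wraps [stats::lm()]; optionally constrains the line through the origin
#' (used for the wobble-total versus maximum wobble-single regression).
#'
#' @param x,y numeric vectors of equal length.
#' @param through_origin fit `y ~ 0 + x` instead of `y ~ x`.
#' @return list of class `linear_fit` with `slope`, `intercept`, `r_squared`,
#'   `n` and the underlying `lm` object as `fit`.
#' @export
linear_fit <- function(x, y, through_origin = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n_min <- if (through_origin) 1L else 2L
  if (length(x) < n_min) stop("too few observations")
  if (!through_origin && stats::sd(x) == 0) stop("degenerate x: zero variance")
  if (through_origin && all(x == 0)) stop("degenerate x: all zero")
  fm <- if (through_origin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
  cf <- stats::coef(fm)
  structure(
    list(slope = unname(cf[["x"]]),
         intercept = if (through_origin) 0 else unname(cf[["(Intercept)"]]),
         r_squared = suppressWarnings(summary(fm)$r.squared),
         n = length(x), fit = fm),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit (n = %d): y = %.4g x %+.4g, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}
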