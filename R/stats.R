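#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic compared against a chi-square distribution
#' with `k - 1` degrees of freedom. With no ties this equals the classic
#' closed form `H = 12/(N(N+1)) * sum(n_j * Rbar_j^2) - 3(N+1)`. When all
#' values across all groups are identical the statistic is 0 with p = 1
#' (degenerate, not an error).
#'
#' @param groups A list of numeric vectors (at least two groups, total
#'   n >= 3) or a named list of samples.
#' @return A list with `statistic` (chi-square scale), `df` and `p`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- lengths(groups)
  if (any(n < 1)) stop("every group needs at least one value")
  N <- length(x)
  if (N < 3) stop("need total n >= 3")
  g <- rep(seq_along(groups), n)
  r <- rank(x) # midranks for ties
  rsum <- tapply(r, g, sum)
  h <- 12 / (N * (N + 1)) * sum(rsum^2 / n) - 3 * (N + 1)
  tie_sizes <- table(x)
  correction <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  statistic <- if (correction == 0) 0 else h / correction
  df <- length(groups) - 1L
  p <- if (correction == 0) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p = p)
}

#' Two-sample test of equal proportions (continuity corrected)
#'
#' Chi-square test of a 2x2 table of successes and failures with the Yates
#' continuity correction `min(0.5, |O - E|)`, one degree of freedom,
#' two-sided p-value. With the correction, tables whose cells all deviate
#' from expectation by at most 0.5 give a statistic of exactly 0. This is
#' the test behind every printed proportion comparison in the summary
#' tables.
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @return A list with `statistic`, `df` and `p`.
#' @examples
#' proportion_test(19, 32, 4, 28) # chi-square 11.01
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  counts <- c(k1, n1, k2, n2)
  if (any(counts < 0) || k1 > n1 || k2 > n2 || n1 < 1 || n2 < 1 ||
      any(counts != round(counts))) {
    stop("invalid counts")
  }
  o <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  if (any(e == 0)) stop("test undefined: a margin of the 2x2 table is zero")
  yates <- min(0.5, abs(o[1, 1] - e[1, 1]))
  statistic <- sum((abs(o - e) - yates)^2 / e)
  list(statistic = statistic, df = 1L,
       p = stats::pchisq(statistic, 1, lower.tail = FALSE))
}

#' Median with 25% and 75% quantiles
#'
#' Linear-interpolation quantiles (type 7, the common statistical-software
#' default), matching fractional quartiles of integer-valued data.
#'
#' @param values Numeric vector, n >= 1.
#' @return Named numeric vector `c(median, q25, q75)`.
#' @export
median_quartiles <- function(values) {
  if (!length(values)) stop("empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Median and mean absolute deviation from the median
#'
#' The "median +/- mean deviation from median" summary convention used for
#' fat scores.
#'
#' @param values Numeric vector, n >= 1.
#' @return Named numeric vector `c(median, mean_abs_dev)`.
#' @export
median_mean_abs_dev <- function(values) {
  if (!length(values)) stop("empty input")
  m <- stats::median(values)
  c(median = m, mean_abs_dev = mean(abs(values - m)))
}
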