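#' @include geometry.R
NULL

.checkPairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("test_mm3", "retest_mm3")
  if (!all(need %in% names(pairs)))
    stop("'pairs' needs columns test_mm3 and retest_mm3")
  if (nrow(pairs) < 1L) stop("need at least one pair")
  v <- c(pairs$test_mm3, pairs$retest_mm3)
  if (anyNA(v) || any(v <= 0)) stop("all volumes must be positive")
  invisible(pairs)
}

#' Within-subject coefficient of variation for test-retest pairs
#'
#' Relative repeatability of a volume measurement from same-subject scan
#' pairs acquired on consecutive days (anatomy assumed unchanged):
#' `wCV = 100 * sqrt( mean_i( d_i^2 / (2 * m_i^2) ) )` where `d_i` and
#' `m_i` are the difference and mean of pair i (the per-pair relative,
#' QIBA-style pooling).  `method = "grand-mean"` gives the alternative
#' pooling `100 * sqrt(mean(d_i^2)/2) / mean(m_i)`.
#'
#' Scale-invariant: multiplying all volumes by a constant leaves it
#' unchanged.
#'
#' @param pairs data.frame with columns `test_mm3`, `retest_mm3` (and
#'   optionally `pair_id`); one row per test-retest pair.
#' @param method pooling convention, `"pairwise"` (default) or
#'   `"grand-mean"`.
#' @return wCV in percent.
#' @examples
#' wcv(data.frame(test_mm3 = 9, retest_mm3 = 11))           # 14.142
#' wcv(data.frame(test_mm3 = c(9, 20), retest_mm3 = c(11, 20)))  # 10
#' @export
wcv <- function(pairs, method = c("pairwise", "grand-mean")) {
  method <- match.arg(method)
  .checkPairs(pairs)
  d <- pairs$retest_mm3 - pairs$test_mm3
  m <- (pairs$retest_mm3 + pairs$test_mm3) / 2
  if (method == "pairwise") 100 * sqrt(mean(d^2 / (2 * m^2)))
  else 100 * sqrt(mean(d^2) / 2) / mean(m)
}

#' Chi-square confidence interval for a wCV estimate
#'
#' The wCV point estimate is scaled by `sqrt(df / qchisq(1 - a/2, df))`
#' and `sqrt(df / qchisq(a/2, df))` with `df = nPairs - 1` degrees of
#' freedom, the construction under which a variance estimate from n pairs
#' follows a scaled chi-square distribution.
#'
#' @param wcvValue wCV point estimate in percent.
#' @param nPairs number of test-retest pairs the estimate is based on
#'   (must be >= 2).
#' @param level confidence level, default 0.95.
#' @return named numeric: `low`, `high` (percent).
#' @examples
#' round(wcvCI(5.3, 13), 1)   # 3.8  8.7
#' round(wcvCI(8.0, 13), 1)   # 5.7 13.2
#' @export
wcvCI <- function(wcvValue, nPairs, level = 0.95) {
  if (nPairs < 2L) stop("confidence interval needs at least 2 pairs")
  if (wcvValue < 0) stop("'wcvValue' must be nonnegative")
  a <- 1 - level
  df <- nPairs - 1
  c(low  = wcvValue * sqrt(df / stats::qchisq(1 - a / 2, df)),
    high = wcvValue * sqrt(df / stats::qchisq(a / 2, df)))
}

#' wCV with confidence interval for a set of pairs
#'
#' @param pairs as in [wcv()].
#' @param level confidence level, default 0.95.
#' @param method pooling convention passed to [wcv()].
#' @return list with `wcv`, `ci_low`, `ci_high` (percent) and `n_pairs`.
#' @export
wcvResult <- function(pairs, level = 0.95, method = "pairwise") {
  w <- wcv(pairs, method = method)
  ci <- if (nrow(pairs) >= 2L) wcvCI(w, nrow(pairs), level) else c(low = NA_real_, high = NA_real_)
  list(wcv = w, ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
       n_pairs = nrow(pairs))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' For repeatability the differences are retest minus test; for accuracy
#' against a reference the caller provides candidate volumes as
#' `retest_mm3` and reference volumes as `test_mm3`, so the bias keeps the
#' sign convention positive = candidate larger than reference.
#'
#' @param pairs data.frame with columns `test_mm3`, `retest_mm3`; at least
#'   2 rows.
#' @return list with `bias` (mean difference, mm^3), `loa_low`,
#'   `loa_high` (`bias -/+ 1.96 * sample SD` of differences), `sd_diff`
#'   and `n`.
#' @examples
#' blandAltman(data.frame(test_mm3 = c(8, 8), retest_mm3 = c(10, 6)))
#' @export
blandAltman <- function(pairs) {
  .checkPairs(pairs)
  if (nrow(pairs) < 2L) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- pairs$retest_mm3 - pairs$test_mm3
  s <- stats::sd(d)
  b <- mean(d)
  list(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Pearson agreement between two volume series
#'
#' @param x,y equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return product-moment correlation in \[-1, 1\].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Repeatability report over methods
#'
#' Computes the wCV (with CI) and Bland-Altman statistics per segmentation
#' method from a long table of test-retest volume pairs, the layout used
#' for the repeatability summary matrix.
#'
#' @param volumes data.frame with columns `pair_id`, `method`,
#'   `test_mm3`, `retest_mm3`.
#' @param level confidence level for the wCV CIs.
#' @return data.frame with one row per method: `method`, `n_pairs`,
#'   `wcv`, `ci_low`, `ci_high`, `bias`, `loa_low`, `loa_high`.
#' @export
repeatabilityReport <- function(volumes, level = 0.95) {
  stopifnot(all(c("pair_id", "method", "test_mm3", "retest_mm3") %in% names(volumes)))
  do.call(rbind, lapply(split(volumes, volumes$method), function(df) {
    w <- wcvResult(df, level = level)
    ba <- if (nrow(df) >= 2L) blandAltman(df) else
      list(bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_)
    data.frame(method = df$method[1], n_pairs = w$n_pairs, wcv = w$wcv,
               ci_low = w$ci_low, ci_high = w$ci_high, bias = ba$bias,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               row.names = NULL)
  }))
}
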