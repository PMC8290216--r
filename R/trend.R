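#' @include AllClasses.R
NULL

## The Mann-Kendall machinery below is implemented from first principles:
## S as the double sum of pairwise signs, the tie-corrected variance of S,
## the continuity-corrected normal approximation, an exact small-sample null
## distribution, and the Sen's slope estimator as the median of pairwise
## slopes. stats::cor.test is used only in the test suite, as an independent
## cross-check.

.assertSeries <- function(values, years, nmin) {
  if (!is.numeric(values) || length(values) < nmin) {
    stop(sprintf("series must be numeric with at least %d values", nmin),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("series values must be finite and non-missing", call. = FALSE)
  }
  if (!is.null(years)) {
    if (length(years) != length(values)) {
      stop("'years' must match the length of the series", call. = FALSE)
    }
    if (any(diff(years) <= 0)) {
      stop("'years' must be strictly increasing", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Mann-Kendall S statistic
#'
#' The sum over all ordered pairs (k < j) of sign(x_j - x_k): +1 when the
#' later value exceeds the earlier, -1 when it is lower, 0 when equal. A
#' strictly increasing series of length n gives S = n(n-1)/2; strictly
#' decreasing gives the negative.
#'
#' @param values numeric series in time order (annual index values).
#' @return Integer-valued numeric S in [-n(n-1)/2, n(n-1)/2].
#' @seealso [mkTest()], [mkVariance()]
#' @examples
#' mkStatistic(c(1, 2, 3, 4, 5))  # 10
#' mkStatistic(c(3, 1, 2))        # -1
#' @export
mkStatistic <- function(values) {
  .assertSeries(values, NULL, 2L)
  n <- length(values)
  s <- 0L
  # upper-triangle pairwise signs, accumulated column-wise to avoid an
  # n x n allocation for long series
  for (k in seq_len(n - 1L)) {
    d <- values[(k + 1L):n] - values[k]
    s <- s + sum(sign(d))
  }
  as.integer(s)
}

#' Tie-corrected variance of the Mann-Kendall S statistic
#'
#' Under the null of no trend with independent observations,
#' var(S) = [n(n-1)(2n+5) - sum_g t_g (t_g - 1)(2 t_g + 5)] / 18,
#' where the sum runs over groups of tied values of extent t_g. With all
#' values distinct this reduces to n(n-1)(2n+5)/18; a fully tied series has
#' variance 0.
#'
#' @param values numeric series (length >= 3).
#' @param tieCorrection logical; set FALSE to drop the tie term.
#' @return Numeric variance, >= 0.
#' @examples
#' mkVariance(1:10)         # 125
#' mkVariance(c(5, 5, 5))   # 0
#' @export
mkVariance <- function(values, tieCorrection = TRUE) {
  .assertSeries(values, NULL, 3L)
  n <- length(values)
  v <- n * (n - 1) * (2 * n + 5)
  if (tieCorrection) {
    t_g <- as.integer(table(values))
    t_g <- t_g[t_g > 1L]
    if (length(t_g)) v <- v - sum(t_g * (t_g - 1) * (2 * t_g + 5))
  }
  v / 18
}

# exact null distribution of S for n distinct values: the distribution of
# (concordant - discordant) pairs over all n! orderings, computed by the
# classical inversion-count convolution. Returns P(S >= s).
.mkExactUpperTail <- function(n, s) {
  # counts[i] = number of permutations with i inversions, i = 0..n(n-1)/2,
  # built by convolving with the uniform kernel of width m at each step
  counts <- 1
  for (m in 2:n) {
    acc <- numeric(length(counts) + m - 1L)
    for (shift in 0:(m - 1L)) {
      idx <- seq_along(counts) + shift
      acc[idx] <- acc[idx] + counts
    }
    counts <- acc
  }
  nmax <- n * (n - 1) / 2
  # S = nmax - 2 * inversions; inversions i maps to S = nmax - 2i
  svals <- nmax - 2 * (seq_along(counts) - 1L)
  sum(counts[svals >= s]) / sum(counts)
}

#' Mann-Kendall trend test for an annual series
#'
#' Tests for a monotonic trend using the S statistic with the tie-corrected
#' variance. By default S is standardised with the +/-1 continuity
#' correction, Z = (S - sign(S)) / sqrt(var(S)) (Z = 0 when S = 0), and the
#' two-sided p-value comes from the standard normal. For short series of
#' distinct values (\code{method = "exact"}, n <= 10) the exact permutation
#' null distribution of S is used instead. A fully tied series is a defined
#' degenerate case: S = 0, Z = 0, p = 1, no trend.
#'
#' @param values numeric series in time order.
#' @param years optional strictly increasing time index (defaults to
#'   1..n); used for the Sen's slope denominator.
#' @param alpha significance level in (0, 1); default 0.10, the conventional
#'   level for climate trend mapping.
#' @param method "normal" (default) or "exact" (n <= 10, no ties).
#' @param continuity logical, apply the +/-1 continuity correction (normal
#'   method only).
#' @param tauMethod "a" (S / (n(n-1)/2), default) or "b" (tie-adjusted
#'   denominator).
#' @param prewhiten logical; remove lag-1 autocorrelation
#'   (x_t - r1 * x_(t-1)) before testing. Off by default: annual index
#'   series are treated as serially independent.
#' @param confLevel optional confidence level in (0, 1) for a Sen's slope
#'   confidence band; NA (default) skips it.
#' @return A [TrendResult-class] object.
#' @examples
#' res <- mkTest(c(3, 5, 4, 8, 7, 9, 12), alpha = 0.10)
#' res
#' @export
mkTest <- function(values, years = NULL, alpha = 0.10,
                   method = c("normal", "exact"),
                   continuity = TRUE, tauMethod = c("a", "b"),
                   prewhiten = FALSE, confLevel = NA_real_) {
  method <- match.arg(method)
  tauMethod <- match.arg(tauMethod)
  .assertSeries(values, years, 3L)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(years)) years <- seq_along(values)

  if (prewhiten && length(values) > 3L) {
    r1 <- stats::cor(values[-1L], values[-length(values)])
    if (is.finite(r1) && abs(r1) < 1) {
      values <- values[-1L] - r1 * values[-length(values)]
      years <- years[-1L]
    }
  }

  n <- length(values)
  S <- mkStatistic(values)
  varS <- mkVariance(values)
  npairs <- n * (n - 1) / 2

  tau <- if (tauMethod == "a") {
    S / npairs
  } else {
    t_g <- as.integer(table(values))
    tx <- sum(t_g * (t_g - 1) / 2)
    denom <- sqrt((npairs - tx) * npairs)  # time index has no ties
    if (denom > 0) S / denom else 0
  }

  if (method == "exact") {
    if (n > 10L) {
      stop("exact method supported only for n <= 10", call. = FALSE)
    }
    if (anyDuplicated(values)) {
      stop("exact method requires distinct values (no ties)", call. = FALSE)
    }
    Z <- if (varS > 0) (S - sign(S) * continuity) / sqrt(varS) else 0
    if (S == 0) {
      p <- 1
    } else {
      p <- min(1, 2 * .mkExactUpperTail(n, abs(S)))
    }
  } else {
    if (varS > 0) {
      Z <- if (S > 0) {
        (S - if (continuity) 1 else 0) / sqrt(varS)
      } else if (S < 0) {
        (S + if (continuity) 1 else 0) / sqrt(varS)
      } else 0
      p <- 2 * stats::pnorm(-abs(Z))
      if (p == 0) p <- .Machine$double.xmin
    } else {
      # all values identical: defined degenerate result
      Z <- 0
      p <- 1
    }
  }

  sen <- sensSlope(values, years, confLevel = confLevel, varS = varS)
  if (!is.list(sen)) sen <- list(slope = sen, confInt = c(NA_real_, NA_real_))
  sig <- p < alpha
  dir <- if (!sig || S == 0) "none" else if (S > 0) "increasing" else
    "decreasing"

  new("TrendResult", S = as.numeric(S), varS = varS, Z = Z, pValue = p,
      tau = tau, senSlope = sen$slope, senConfInt = sen$confInt,
      alpha = alpha, significant = sig, direction = dir, n = as.integer(n))
}

#' Sen's slope: median of pairwise slopes
#'
#' The robust trend-magnitude estimator: the median over all ordered pairs
#' (k < j) of (x_j - x_k) / (t_j - t_k), in units per year when the time
#' index is calendar years. With an even number of pairs the midpoint of the
#' middle two slopes is returned. Optionally a distribution-free confidence
#' band is attached, from the ranks
#' (N -/+ z * sqrt(var(S))) / 2 of the sorted pairwise slopes.
#'
#' @param values numeric series in time order (length >= 2).
#' @param years optional strictly increasing time index (defaults 1..n).
#' @param confLevel confidence level in (0, 1), or NA (default) for no band.
#' @param varS optional precomputed tie-corrected variance of S (computed
#'   when needed otherwise).
#' @return For the default call, the numeric slope. When \code{confLevel}
#'   is given, a list with elements \code{slope} and \code{confInt}.
#' @examples
#' sensSlope(c(1, 2, 4), years = c(1, 2, 3))  # 1.5
#' sensSlope(5 + 2 * (0:9))                   # exactly 2
#' @export
sensSlope <- function(values, years = NULL, confLevel = NA_real_,
                      varS = NULL) {
  .assertSeries(values, years, 2L)
  if (is.null(years)) years <- seq_along(values)
  n <- length(values)
  # materialise all pairwise slopes
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  slopes <- (values[ij[, 2L]] - values[ij[, 1L]]) /
    (years[ij[, 2L]] - years[ij[, 1L]])
  slope <- stats::median(slopes)

  confInt <- c(NA_real_, NA_real_)
  if (!is.na(confLevel)) {
    if (confLevel <= 0 || confLevel >= 1) {
      stop("'confLevel' must lie in (0, 1)", call. = FALSE)
    }
    if (is.null(varS)) {
      varS <- if (n >= 3L) mkVariance(values) else 0
    }
    if (varS > 0) {
      z <- stats::qnorm(1 - (1 - confLevel) / 2)
      N <- length(slopes)
      srt <- sort(slopes)
      lo <- max(1L, floor((N - z * sqrt(varS)) / 2))
      hi <- min(N, ceiling((N + z * sqrt(varS)) / 2) + 1L)
      confInt <- c(srt[lo], srt[hi])
    }
  }

  if (is.na(confLevel)) slope else list(slope = slope, confInt = confInt)
}

#' Tidy one-row summary of a trend test
#'
#' @param x a [TrendResult-class] object.
#' @return A one-row data.frame with columns n, S, var_S, Z, p_value, tau,
#'   sen_slope, alpha, significant, direction.
#' @examples
#' as.data.frame(mkTest(c(1, 3, 2, 5, 4, 6)))
#' @export
trendResultRow <- function(x) {
  stopifnot(is(x, "TrendResult"))
  data.frame(n = x@n, S = x@S, var_S = x@varS, Z = x@Z, p_value = x@pValue,
             tau = x@tau, sen_slope = x@senSlope, alpha = x@alpha,
             significant = x@significant, direction = x@direction,
             stringsAsFactors = FALSE)
}

#' @describeIn trendResultRow method for base::as.data.frame
#' @param row.names,optional,... ignored (base generic signature).
#' @exportS3Method base::as.data.frame
as.data.frame.TrendResult <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  trendResultRow(x)
}

#' Trend test on a two-column (year, value) table or file
#'
#' Convenience wrapper: reads a CSV with columns year and value (or takes a
#' data.frame directly), runs [mkTest()] and returns the one-row summary.
#'
#' @param x path to a CSV file, or a data.frame with columns year, value.
#' @param ... passed to [mkTest()] (alpha, method, ...).
#' @return One-row data.frame as in [trendResultRow()].
#' @export
trendFromTable <- function(x, ...) {
  df <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  if (!all(c("year", "value") %in% names(df))) {
    stop("input must have columns 'year' and 'value'", call. = FALSE)
  }
  df <- df[order(df$year), , drop = FALSE]
  trendResultRow(mkTest(df$value, years = df$year, ...))
}
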