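#' @include AllClasses.R
NULL

# seasonal mean temperature: single cosine harmonic peaking mid-July
# (DOY 196), the simplest shape giving the warm/cold season contrast the
# indices respond to. Evaluated on a leap-invariant pseudo day-of-year
# (Feb 29 repeats Feb 28) so every calendar date has the same climatology in
# every year and month-day window sums are identical across years.
.seasonalCycle <- function(pdoy, meanT, amplitude) {
  meanT + amplitude * cos(2 * pi * (pdoy - 196) / 365)
}

# pseudo day-of-year: 1..365 in all years; in leap years Feb 29 maps onto
# Feb 28 and later days shift down by one
.pseudoDoy <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4L == 0L & yr %% 100L != 0L) | yr %% 400L == 0L
  doy[leap & doy >= 60L] <- doy[leap & doy >= 60L] - 1L
  doy
}

.expandField <- function(x, nRows, nCols) {
  if (is.matrix(x)) x else matrix(x, nRows, nCols)
}

#' Generate a synthetic daily gridded climate record
#'
#' Draws a gap-free daily tmin/tmax/precipitation record on a regular grid
#' from a transparent stochastic model:
#' \itemize{
#'   \item daily mean temperature = annual mean + seasonal cosine harmonic
#'     (peak mid-July) + north-south gradient x row + linear trend x
#'     (year - start year) + AR(1) noise (marginal sd \code{dailyNoiseSd});
#'   \item tmax/tmin = mean +/- half the diurnal range, the half-range
#'     independently perturbed (sd proportional to \code{dailyNoiseSd}) but
#'     floored at 0 so tmax >= tmin always holds;
#'   \item precipitation: each day is wet with its month's probability
#'     (optionally with 2-state Markov persistence); wet-day amounts are
#'     gamma(shape, scale) mm, multiplied by a linear trend factor
#'     (1 + pTrend (year - start year) / reference annual total) and clamped
#'     nonnegative.
#' }
#' Identical \code{config} (including seed) gives bit-identical output. All
#' pixels' noise streams are mutually independent.
#'
#' @param config a [GeneratorConfig-class] object.
#' @return A [ClimateGrid-class] covering \code{nYears} full calendar years.
#' @examples
#' g <- generateDailyClimate(GeneratorConfig(nYears = 3, nRows = 2,
#'                                           nCols = 2, seed = 7))
#' g
#' @export
generateDailyClimate <- function(config) {
  if (!is(config, "GeneratorConfig")) {
    stop("'config' must be a GeneratorConfig", call. = FALSE)
  }
  validObject(config)

  nR <- config@nRows
  nC <- config@nCols
  y0 <- config@startYear
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y0 + config@nYears - 1L)),
               by = "day")
  nT <- length(dates)
  nP <- nR * nC
  pdoy <- .pseudoDoy(dates)
  yearIdx <- as.POSIXlt(dates)$year + 1900L - y0  # 0-based year offset
  month <- as.POSIXlt(dates)$mon + 1L

  set.seed(config@seed)

  ## ---- temperature ----
  clim <- .seasonalCycle(pdoy, config@meanAnnualT, config@seasonalAmplitude)
  gradRow <- config@nsGradient * (seq_len(nR) - 1L)          # per-row offset
  tTrend <- .expandField(config@tTrend, nR, nC)              # degC / yr

  # AR(1) noise, one independent stream per pixel, marginal sd dailyNoiseSd
  if (config@dailyNoiseSd > 0) {
    innovSd <- config@dailyNoiseSd * sqrt(1 - config@ar1Coeff^2)
    eps <- matrix(stats::rnorm(nT * nP, sd = innovSd), nT, nP)
    if (config@ar1Coeff > 0) {
      eps <- stats::filter(eps, config@ar1Coeff, method = "recursive")
      eps <- matrix(as.numeric(eps), nT, nP)
    }
  } else {
    eps <- matrix(0, nT, nP)
  }

  # mean-field: time x pixel
  tmean <- matrix(clim, nT, nP) + eps
  rowOfPix <- rep(seq_len(nR), times = nC)
  tmean <- tmean + matrix(gradRow[rowOfPix], nT, nP, byrow = TRUE)
  tmean <- tmean + outer(yearIdx, as.vector(tTrend))

  # diurnal spread with a small perturbation tied to the noise level
  if (config@dailyNoiseSd > 0) {
    halfRange <- pmax(config@diurnalRange / 2 +
                        matrix(stats::rnorm(nT * nP,
                                            sd = 0.15 * config@dailyNoiseSd),
                               nT, nP), 0)
  } else {
    halfRange <- matrix(config@diurnalRange / 2, nT, nP)
  }
  tmax <- tmean + halfRange
  tmin <- tmean - halfRange

  ## ---- precipitation ----
  pWet <- config@wetProbByMonth[month]  # per-day probability
  if (is.na(config@wetPersistence)) {
    wet <- matrix(stats::runif(nT * nP), nT, nP) < pWet
  } else {
    # 2-state Markov occurrence preserving the monthly wet frequency pi:
    # p11 = pi + w (1 - pi) and p01 = pi (1 - w) keep the stationary wet
    # probability at pi for persistence weight w
    w <- config@wetPersistence
    u <- matrix(stats::runif(nT * nP), nT, nP)
    wet <- matrix(FALSE, nT, nP)
    p11 <- pWet + w * (1 - pWet)
    p01 <- pmax(0, pWet * (1 - p11) / pmax(1e-12, 1 - pWet))
    wet[1L, ] <- u[1L, ] < pWet[1L]
    for (t in 2:nT) {
      pcond <- ifelse(wet[t - 1L, ], p11[t], p01[t])
      wet[t, ] <- u[t, ] < pcond
    }
  }

  pTrend <- .expandField(config@pTrend, nR, nC)
  # reference: expected annual total under the untrended model, used to turn
  # an additive mm/yr trend into a multiplicative wet-day scaling
  refAnnual <- sum(config@wetProbByMonth * c(31, 28.25, 31, 30, 31, 30, 31,
                                             31, 30, 31, 30, 31)) *
    config@precipShape * config@precipScale
  scaleFac <- 1 + outer(yearIdx, as.vector(pTrend)) / refAnnual
  scaleFac[scaleFac < 0] <- 0

  nWet <- sum(wet)
  amounts <- matrix(0, nT, nP)
  if (nWet > 0) {
    amounts[wet] <- stats::rgamma(nWet, shape = config@precipShape,
                                  scale = config@precipScale)
  }
  precip <- amounts * scaleFac

  dim(tmin) <- c(nT, nR, nC)
  dim(tmax) <- c(nT, nR, nC)
  dim(precip) <- c(nT, nR, nC)
  ClimateGrid(dates = dates, tmin = tmin, tmax = tmax, precip = precip,
              spacing = c(1, 1))
}

#' Generate a 1-D annual series with a linear trend
#'
#' x_t = intercept + slope * t + eps_t with iid normal noise, t = 0..n-1.
#' The basic fixture for exercising the trend statistics: the injected slope
#' is the quantity the Sen's estimator should recover.
#'
#' @param n series length (>= 3).
#' @param intercept,slope linear model coefficients (slope per year).
#' @param noiseSd standard deviation of the iid noise (>= 0).
#' @param seed integer RNG seed.
#' @return Numeric vector of length n.
#' @examples
#' generateAnnualSeries(5, 0, 2, 0, seed = 1)   # 0 2 4 6 8
#' @export
generateAnnualSeries <- function(n, intercept = 0, slope = 0, noiseSd = 1,
                                 seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 3) {
    stop("'n' must be a single integer >= 3", call. = FALSE)
  }
  if (noiseSd < 0) stop("'noiseSd' must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  t <- seq_len(n) - 1
  intercept + slope * t + stats::rnorm(n, sd = noiseSd)
}
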