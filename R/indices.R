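#' @include AllClasses.R
NULL

## Window handling -----------------------------------------------------------
## All index windows are inclusive "MM-DD" spans on the real calendar of the
## labelled year. Missing data inside a required window invalidates that
## pixel-year (NA), never a partial sum: partial sums would bias trend
## slopes.

.windowDates <- function(year, startMD, endMD) {
  s <- as.Date(sprintf("%d-%s", year, startMD))
  e <- as.Date(sprintf("%d-%s", year, endMD))
  if (is.na(s)) s <- as.Date(sprintf("%d-03-01", year)) - 1  # Feb 29 fallback
  if (is.na(e)) e <- as.Date(sprintf("%d-03-01", year)) - 1
  c(s, e)
}

# indices into 'dates' covering [start, end]; NULL when not fully covered
.windowIdx <- function(dates, start, end) {
  if (start < dates[1L] || end > dates[length(dates)]) return(NULL)
  which(dates >= start & dates <= end)
}

# collapse a (days x row x col) slab with a summary over days, propagating
# NA (any missing day -> invalid pixel-year)
.slabApply <- function(x, idx, fn) {
  sub <- x[idx, , , drop = FALSE]
  apply(sub, c(2L, 3L), fn)
}

#' Daily mean temperature convention
#'
#' The arithmetic midpoint (tmin + tmax) / 2 used throughout the index
#' computations (GDD accumulation, windowed temperature means).
#'
#' @param tmin,tmax numeric, deg C; tmax must be >= tmin element-wise.
#' @return Numeric, same shape as the inputs.
#' @examples
#' dailyMeanTemperature(10, 20)  # 15
#' @export
dailyMeanTemperature <- function(tmin, tmax) {
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop("'tmax' must be >= 'tmin'", call. = FALSE)
  }
  (tmin + tmax) / 2
}

#' Growing degree days for one year
#'
#' Accumulated heat above the base temperature over the growing season
#' (default April 1 to October 31, base 10 deg C). Two conventions:
#' \describe{
#'   \item{simple}{sum of max(0, (tmin + tmax)/2 - base) over season days;}
#'   \item{corn}{tmin and tmax each clamped to [base, 30] before averaging,
#'     then base subtracted.}
#' }
#'
#' @param grid a [ClimateGrid-class].
#' @param year calendar year to evaluate.
#' @param config an [IndexConfig-class].
#' @return row x col matrix of accumulated degree-days (NA where any season
#'   day is missing).
#' @examples
#' g <- generateDailyClimate(GeneratorConfig(nYears = 3, nRows = 2,
#'                                           nCols = 2, seed = 3))
#' growingDegreeDays(g, 1984)
#' @export
growingDegreeDays <- function(grid, year, config = IndexConfig()) {
  w <- .windowDates(year, config@seasonStart, config@seasonEnd)
  idx <- .windowIdx(grid@dates, w[1L], w[2L])
  d <- dim(grid@tmin)[2:3]
  if (is.null(idx)) return(matrix(NA_real_, d[1L], d[2L]))
  tmin <- grid@tmin[idx, , , drop = FALSE]
  tmax <- grid@tmax[idx, , , drop = FALSE]
  if (config@gddMethod == "corn") {
    tmin <- pmin(pmax(tmin, config@gddBase), 30)
    tmax <- pmin(pmax(tmax, config@gddBase), 30)
    dd <- (tmin + tmax) / 2 - config@gddBase
  } else {
    dd <- pmax((tmin + tmax) / 2 - config@gddBase, 0)  # first arg keeps dims
  }
  apply(dd, c(2L, 3L), sum)  # NA propagates: missing day -> invalid year
}

#' Frost-free season length for one year
#'
#' The freeze-to-freeze definition of the growing season: FFD equals the
#' day-of-year of the first fall freeze minus the day-of-year of the last
#' spring freeze, where a freeze day has tmin <= \code{freezeThreshold}
#' (default 0 deg C). The last spring freeze is searched January 1 to
#' June 30 (none found: DOY 0); the first fall freeze July 1 to December 31
#' (none found: DOY 366). The result lies in [0, 366]; a year with no freeze
#' at all scores 366.
#'
#' @inheritParams growingDegreeDays
#' @return row x col matrix of day counts (NA where the calendar year is
#'   incompletely observed).
#' @export
frostFreeDays <- function(grid, year, config = IndexConfig()) {
  yStart <- as.Date(sprintf("%d-01-01", year))
  yEnd <- as.Date(sprintf("%d-12-31", year))
  idx <- .windowIdx(grid@dates, yStart, yEnd)
  d <- dim(grid@tmin)[2:3]
  if (is.null(idx)) return(matrix(NA_real_, d[1L], d[2L]))
  tmin <- grid@tmin[idx, , , drop = FALSE]
  doy <- as.POSIXlt(grid@dates[idx])$yday + 1L
  jun30 <- max(doy[grid@dates[idx] <= as.Date(sprintf("%d-06-30", year))])
  thr <- config@freezeThreshold
  springDays <- which(doy <= jun30)
  fallDays <- which(doy > jun30)
  out <- matrix(NA_real_, d[1L], d[2L])
  for (r in seq_len(d[1L])) {
    for (cc in seq_len(d[2L])) {
      x <- tmin[, r, cc]
      if (anyNA(x)) next
      fr <- x <= thr
      lastSpring <- if (any(fr[springDays])) {
        max(doy[springDays][fr[springDays]])
      } else 0
      firstFall <- if (any(fr[fallDays])) {
        min(doy[fallDays][fr[fallDays]])
      } else 366
      out[r, cc] <- max(0, firstFall - lastSpring)
    }
  }
  out
}

#' Frequency of damaging cold days for one winter
#'
#' Counts days with tmin strictly below \code{coldThreshold} (default
#' -20 deg C, near the cold-damage boundary for V. vinifera) within the
#' winter window running from \code{coldWindowStart} of the preceding year
#' to \code{coldWindowEnd} of the labelled year (defaults November 1 to
#' March 31). The first year of a record is invalid when its preceding
#' November-December is unavailable.
#'
#' @inheritParams growingDegreeDays
#' @return row x col matrix of day counts (NA where the winter window is
#'   incompletely observed).
#' @export
coldDayFrequency <- function(grid, year, config = IndexConfig()) {
  s <- as.Date(sprintf("%d-%s", year - 1L, config@coldWindowStart))
  e <- as.Date(sprintf("%d-%s", year, config@coldWindowEnd))
  idx <- .windowIdx(grid@dates, s, e)
  d <- dim(grid@tmin)[2:3]
  if (is.null(idx)) return(matrix(NA_real_, d[1L], d[2L]))
  thr <- config@coldThreshold
  .slabApply(grid@tmin, idx, function(x) sum(x < thr))
}

#' Windowed precipitation total for one year
#'
#' Arithmetic sum of daily precipitation over an inclusive month-day window
#' of the given year.
#'
#' @inheritParams growingDegreeDays
#' @param window length-2 character c(start, end) in "MM-DD" form.
#' @return row x col matrix of totals in mm (NA where any window day is
#'   missing).
#' @examples
#' g <- generateDailyClimate(GeneratorConfig(nYears = 3, nRows = 2,
#'                                           nCols = 2, seed = 3))
#' windowedPrecipTotal(g, 1984, c("04-01", "10-31"))
#' @export
windowedPrecipTotal <- function(grid, year, window = c("04-01", "10-31")) {
  w <- .windowDates(year, window[1L], window[2L])
  idx <- .windowIdx(grid@dates, w[1L], w[2L])
  d <- dim(grid@precip)[2:3]
  if (is.null(idx)) return(matrix(NA_real_, d[1L], d[2L]))
  .slabApply(grid@precip, idx, sum)
}

#' Windowed mean temperature for one year
#'
#' Mean of the daily mean temperature ((tmin + tmax)/2) over an inclusive
#' month-day window of the given year.
#'
#' @inheritParams windowedPrecipTotal
#' @return row x col matrix in deg C (NA where any window day is missing).
#' @export
windowedTempMean <- function(grid, year, window = c("04-01", "10-31")) {
  w <- .windowDates(year, window[1L], window[2L])
  idx <- .windowIdx(grid@dates, w[1L], w[2L])
  d <- dim(grid@tmin)[2:3]
  if (is.null(idx)) return(matrix(NA_real_, d[1L], d[2L]))
  tm <- (grid@tmin[idx, , , drop = FALSE] +
           grid@tmax[idx, , , drop = FALSE]) / 2
  apply(tm, c(2L, 3L), mean)
}

#' Compute the eight annual agroclimatic index cubes
#'
#' Evaluates, for every complete calendar year in the grid, the eight
#' viticulture-relevant variables:
#' \tabular{lll}{
#'   GDD \tab degree-days \tab growing degree days, base \code{gddBase} \cr
#'   FCD \tab days \tab winter days with tmin < \code{coldThreshold} \cr
#'   FFD \tab days \tab frost-free season length \cr
#'   SPRING_T \tab deg C \tab mean spring temperature \cr
#'   PRECIP_GROWTH \tab mm \tab precipitation, critical growth window \cr
#'   PRECIP_ROT \tab mm \tab precipitation, veraison-harvest rot window \cr
#'   GST \tab deg C \tab mean growing-season temperature \cr
#'   GS_PRECIP \tab mm \tab total growing-season precipitation \cr
#' }
#' Every cube shares the common year axis. A pixel-year is NA exactly when
#' some day required by that variable's window is missing; in particular the
#' first year's FCD is NA because its preceding November-December precedes
#' the record.
#'
#' @param grid a [ClimateGrid-class] spanning at least one full calendar
#'   year.
#' @param config an [IndexConfig-class].
#' @return Named list of eight [IndexCube-class] objects.
#' @examples
#' g <- generateDailyClimate(GeneratorConfig(nYears = 4, nRows = 2,
#'                                           nCols = 2, seed = 3))
#' cubes <- computeAnnualIndices(g)
#' cubes$GDD
#' @export
computeAnnualIndices <- function(grid, config = IndexConfig()) {
  if (!is(grid, "ClimateGrid")) {
    stop("'grid' must be a ClimateGrid", call. = FALSE)
  }
  dts <- grid@dates
  yrs <- sort(unique(as.POSIXlt(dts)$year + 1900L))
  full <- vapply(yrs, function(y) {
    !is.null(.windowIdx(dts, as.Date(sprintf("%d-01-01", y)),
                        as.Date(sprintf("%d-12-31", y))))
  }, logical(1L))
  yrs <- yrs[full]
  if (!length(yrs)) {
    stop("grid contains no complete calendar year", call. = FALSE)
  }
  d <- dim(grid@tmin)[2:3]
  nY <- length(yrs)
  mk <- function(fn) {
    arr <- array(NA_real_, c(nY, d[1L], d[2L]))
    for (i in seq_len(nY)) arr[i, , ] <- fn(yrs[i])
    arr
  }
  sw <- c(config@springStart, config@springEnd)
  gw <- c(config@growthStart, config@growthEnd)
  rw <- c(config@rotStart, config@rotEnd)
  gs <- c(config@seasonStart, config@seasonEnd)
  list(
    GDD = IndexCube("GDD", yrs,
                    mk(function(y) growingDegreeDays(grid, y, config)),
                    units = "degree-days"),
    FCD = IndexCube("FCD", yrs,
                    mk(function(y) coldDayFrequency(grid, y, config)),
                    units = "days"),
    FFD = IndexCube("FFD", yrs,
                    mk(function(y) frostFreeDays(grid, y, config)),
                    units = "days"),
    SPRING_T = IndexCube("SPRING_T", yrs,
                         mk(function(y) windowedTempMean(grid, y, sw)),
                         units = "degC"),
    PRECIP_GROWTH = IndexCube("PRECIP_GROWTH", yrs,
                              mk(function(y) windowedPrecipTotal(grid, y, gw)),
                              units = "mm"),
    PRECIP_ROT = IndexCube("PRECIP_ROT", yrs,
                           mk(function(y) windowedPrecipTotal(grid, y, rw)),
                           units = "mm"),
    GST = IndexCube("GST", yrs,
                    mk(function(y) windowedTempMean(grid, y, gs)),
                    units = "degC"),
    GS_PRECIP = IndexCube("GS_PRECIP", yrs,
                          mk(function(y) windowedPrecipTotal(grid, y, gs)),
                          units = "mm")
  )
}
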