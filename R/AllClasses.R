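#' @include AllGenerics.R
NULL

## -------------------------------------------------------------------------
## GeneratorConfig
## -------------------------------------------------------------------------

#' Configuration for the stochastic daily weather generator
#'
#' Holds every knob of the synthetic daily-climate model: a seasonal
#' temperature cycle with a north-south gradient, AR(1) day-to-day noise, a
#' linear warming trend, and a wet-day/amount precipitation model with an
#' optional linear trend in wet-day amounts. Defaults describe a cool-climate
#' grape-growing region of the Great Lakes type (Michigan's Lower Peninsula):
#' a 37-year record starting in 1983 on a 20 x 20 grid.
#'
#' @slot nYears integer, number of complete calendar years (>= 3).
#' @slot startYear integer, first calendar year.
#' @slot nRows,nCols integer, grid shape (rows indexed south to north).
#' @slot meanAnnualT numeric, annual mean temperature (deg C) at row 1.
#' @slot seasonalAmplitude numeric, half peak-to-trough amplitude of the
#'   single-harmonic seasonal cycle (deg C), peaking mid-July.
#' @slot diurnalRange numeric, mean tmax - tmin spread (deg C).
#' @slot nsGradient numeric, temperature change per row step (deg C/row);
#'   negative values cool the grid toward higher row indices (northward).
#' @slot ar1Coeff numeric in [0, 1), lag-1 autocorrelation of daily
#'   temperature noise.
#' @slot dailyNoiseSd numeric >= 0, marginal standard deviation (deg C) of the
#'   daily temperature noise; also scales the diurnal-range perturbation, so
#'   zero gives a fully deterministic temperature field.
#' @slot tTrend numeric scalar or nRows x nCols matrix, linear warming trend
#'   (deg C per year) applied to daily temperatures.
#' @slot wetProbByMonth numeric length 12 in [0, 1], probability a day is wet,
#'   by calendar month.
#' @slot precipShape,precipScale numeric > 0, gamma shape and scale (mm) of
#'   wet-day precipitation amounts.
#' @slot pTrend numeric scalar or matrix, linear trend in annual precipitation
#'   (mm per year), realised by scaling wet-day amounts.
#' @slot wetPersistence numeric, NA for independent (Bernoulli) wet-day
#'   occurrence, or a value in [0, 1) adding 2-state Markov persistence: the
#'   wet-after-wet probability is inflated toward 1 by this weight while the
#'   monthly wet-day frequency is preserved.
#' @slot seed integer, RNG seed; identical seed and config give bit-identical
#'   output.
#'
#' @param nYears,startYear,nRows,nCols,meanAnnualT,seasonalAmplitude
#'   see slots.
#' @param diurnalRange,nsGradient,ar1Coeff,dailyNoiseSd,tTrend see slots.
#' @param wetProbByMonth,precipShape,precipScale,pTrend,wetPersistence,seed
#'   see slots.
#' @return \code{GeneratorConfig()} returns a validated
#'   \code{GeneratorConfig} object.
#' @seealso [generateDailyClimate()]
#' @examples
#' cfg <- GeneratorConfig(nYears = 5, nRows = 4, nCols = 4, tTrend = 0.05)
#' cfg
#' @aliases GeneratorConfig
#' @export GeneratorConfig
#' @exportClass GeneratorConfig
GeneratorConfig <- setClass(
  "GeneratorConfig",
  slots = c(
    nYears = "integer", startYear = "integer",
    nRows = "integer", nCols = "integer",
    meanAnnualT = "numeric", seasonalAmplitude = "numeric",
    diurnalRange = "numeric", nsGradient = "numeric",
    ar1Coeff = "numeric", dailyNoiseSd = "numeric",
    tTrend = "ANY",
    wetProbByMonth = "numeric",
    precipShape = "numeric", precipScale = "numeric",
    pTrend = "ANY",
    wetPersistence = "numeric",
    seed = "integer"
  )
)

.checkTrendField <- function(value, name, nRows, nCols) {
  if (!is.numeric(value)) {
    return(sprintf("'%s' must be numeric (scalar or matrix)", name))
  }
  if (is.matrix(value)) {
    if (!identical(dim(value), c(nRows, nCols))) {
      return(sprintf("'%s' matrix must be nRows x nCols (%d x %d)",
                     name, nRows, nCols))
    }
  } else if (length(value) != 1L) {
    return(sprintf("'%s' must be a scalar or an nRows x nCols matrix", name))
  }
  if (anyNA(value)) return(sprintf("'%s' contains NA", name))
  NULL
}

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (length(object@nYears) != 1L || is.na(object@nYears) ||
      object@nYears < 3L) {
    msg <- c(msg, "'nYears' must be a single integer >= 3")
  }
  if (object@nRows < 1L || object@nCols < 1L) {
    msg <- c(msg, "'nRows' and 'nCols' must be positive")
  }
  if (length(object@ar1Coeff) != 1L || is.na(object@ar1Coeff) ||
      object@ar1Coeff < 0 || object@ar1Coeff >= 1) {
    msg <- c(msg, "'ar1Coeff' must lie in [0, 1)")
  }
  if (object@dailyNoiseSd < 0) msg <- c(msg, "'dailyNoiseSd' must be >= 0")
  if (object@diurnalRange < 0) msg <- c(msg, "'diurnalRange' must be >= 0")
  if (length(object@wetProbByMonth) != 12L ||
      anyNA(object@wetProbByMonth) ||
      any(object@wetProbByMonth < 0 | object@wetProbByMonth > 1)) {
    msg <- c(msg, "'wetProbByMonth' must be 12 probabilities in [0, 1]")
  }
  if (object@precipShape <= 0) msg <- c(msg, "'precipShape' must be > 0")
  if (object@precipScale <= 0) msg <- c(msg, "'precipScale' must be > 0")
  if (!is.na(object@wetPersistence) &&
      (object@wetPersistence < 0 || object@wetPersistence >= 1)) {
    msg <- c(msg, "'wetPersistence' must be NA or in [0, 1)")
  }
  msg <- c(msg,
           .checkTrendField(object@tTrend, "tTrend",
                            object@nRows, object@nCols),
           .checkTrendField(object@pTrend, "pTrend",
                            object@nRows, object@nCols))
  if (length(msg)) msg else TRUE
})

#' @rdname GeneratorConfig-class
#' @usage NULL
GeneratorConfig <- function(nYears = 37, startYear = 1983,
                            nRows = 20, nCols = 20,
                            meanAnnualT = 8.5, seasonalAmplitude = 13.5,
                            diurnalRange = 10, nsGradient = -0.05,
                            ar1Coeff = 0.6, dailyNoiseSd = 3.2,
                            tTrend = 0,
                            wetProbByMonth = c(0.42, 0.36, 0.36, 0.36, 0.34,
                                               0.32, 0.30, 0.31, 0.33, 0.35,
                                               0.40, 0.43),
                            precipShape = 0.9, precipScale = 8.5,
                            pTrend = 0, wetPersistence = NA_real_,
                            seed = 1L) {
  new("GeneratorConfig",
      nYears = as.integer(nYears), startYear = as.integer(startYear),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      meanAnnualT = as.numeric(meanAnnualT),
      seasonalAmplitude = as.numeric(seasonalAmplitude),
      diurnalRange = as.numeric(diurnalRange),
      nsGradient = as.numeric(nsGradient),
      ar1Coeff = as.numeric(ar1Coeff),
      dailyNoiseSd = as.numeric(dailyNoiseSd),
      tTrend = if (is.matrix(tTrend)) tTrend else as.numeric(tTrend),
      wetProbByMonth = as.numeric(wetProbByMonth),
      precipShape = as.numeric(precipShape),
      precipScale = as.numeric(precipScale),
      pTrend = if (is.matrix(pTrend)) pTrend else as.numeric(pTrend),
      wetPersistence = as.numeric(wetPersistence),
      seed = as.integer(seed))
}

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat(sprintf("  %d years from %d on a %d x %d grid\n",
              object@nYears, object@startYear, object@nRows, object@nCols))
  cat(sprintf("  mean annual T %.1f degC, amplitude %.1f, diurnal range %.1f\n",
              object@meanAnnualT, object@seasonalAmplitude,
              object@diurnalRange))
  tt <- if (is.matrix(object@tTrend)) "per-pixel field" else
    sprintf("%.3f degC/yr", object@tTrend)
  pt <- if (is.matrix(object@pTrend)) "per-pixel field" else
    sprintf("%.2f mm/yr", object@pTrend)
  cat(sprintf("  trends: temperature %s, precipitation %s\n", tt, pt))
  cat(sprintf("  noise sd %.2f, AR(1) %.2f, seed %d\n",
              object@dailyNoiseSd, object@ar1Coeff, object@seed))
})

## -------------------------------------------------------------------------
## ClimateGrid
## -------------------------------------------------------------------------

#' Daily gridded climate: tmin, tmax and precipitation cubes
#'
#' Container for a gap-free daily record of minimum and maximum temperature
#' (deg C) and precipitation (mm) on a regular grid. Each variable is a
#' time x row x col array; missing observations are NA. The calendar is
#' real (leap days present), strictly increasing and gap-free.
#'
#' @slot dates Date vector, one entry per day, consecutive.
#' @slot tmin,tmax numeric arrays (time x row x col), deg C, tmax >= tmin
#'   wherever both are present.
#' @slot precip numeric array (time x row x col), mm, nonnegative.
#' @slot origin numeric length 2, coordinates of the (1, 1) cell centre.
#' @slot spacing numeric length 2, cell spacing in grid units.
#'
#' @seealso [generateDailyClimate()], [computeAnnualIndices()],
#'   [writeClimateGrid()]
#' @aliases ClimateGrid
#' @export ClimateGrid
#' @exportClass ClimateGrid
ClimateGrid <- setClass(
  "ClimateGrid",
  slots = c(
    dates = "Date",
    tmin = "array", tmax = "array", precip = "array",
    origin = "numeric", spacing = "numeric"
  )
)

setValidity("ClimateGrid", function(object) {
  msg <- character()
  d <- dim(object@tmin)
  if (length(d) != 3L) msg <- c(msg, "'tmin' must be a 3-d array")
  if (!identical(d, dim(object@tmax)) || !identical(d, dim(object@precip))) {
    msg <- c(msg, "'tmin', 'tmax' and 'precip' must share dimensions")
  }
  if (length(object@dates) != d[1L]) {
    msg <- c(msg, "length of 'dates' must equal the time dimension")
  }
  if (length(object@dates) > 1L &&
      !all(diff(as.integer(object@dates)) == 1L)) {
    msg <- c(msg, "'dates' must be strictly increasing, gap-free daily")
  }
  if (any(object@tmax < object@tmin, na.rm = TRUE)) {
    msg <- c(msg, "'tmax' must be >= 'tmin' wherever both are present")
  }
  if (any(object@precip < 0, na.rm = TRUE)) {
    msg <- c(msg, "'precip' must be nonnegative")
  }
  if (length(object@origin) != 2L || length(object@spacing) != 2L) {
    msg <- c(msg, "'origin' and 'spacing' must have length 2")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ClimateGrid-class
#' @param dates,tmin,tmax,precip,origin,spacing see slots.
#' @usage NULL
ClimateGrid <- function(dates, tmin, tmax, precip,
                        origin = c(0, 0), spacing = c(1, 1)) {
  new("ClimateGrid", dates = as.Date(dates), tmin = tmin, tmax = tmax,
      precip = precip, origin = as.numeric(origin),
      spacing = as.numeric(spacing))
}

#' @rdname viticlim-accessors
#' @export
setMethod("climDates", "ClimateGrid", function(x) x@dates)
#' @rdname viticlim-accessors
#' @export
setMethod("climTmin", "ClimateGrid", function(x) x@tmin)
#' @rdname viticlim-accessors
#' @export
setMethod("climTmax", "ClimateGrid", function(x) x@tmax)
#' @rdname viticlim-accessors
#' @export
setMethod("climPrecip", "ClimateGrid", function(x) x@precip)
#' @rdname viticlim-accessors
#' @export
setMethod("gridShape", "ClimateGrid", function(x) dim(x@tmin)[2:3])

setMethod("show", "ClimateGrid", function(object) {
  d <- dim(object@tmin)
  cat("ClimateGrid\n")
  cat(sprintf("  %d days (%s to %s) on a %d x %d grid\n",
              d[1L], format(object@dates[1L]),
              format(object@dates[length(object@dates)]), d[2L], d[3L]))
  nmiss <- sum(is.na(object@tmin)) + sum(is.na(object@tmax)) +
    sum(is.na(object@precip))
  cat(sprintf("  tmin/tmax [degC], precip [mm]; %d missing cells\n", nmiss))
})

## -------------------------------------------------------------------------
## IndexConfig
## -------------------------------------------------------------------------

#' Thresholds and date windows defining the agroclimatic indices
#'
#' All calendar windows are inclusive "MM-DD" spans on the real (leap-aware)
#' calendar. The winter cold window runs from \code{coldWindowStart} of the
#' preceding year to \code{coldWindowEnd} of the labelled year.
#'
#' @slot gddBase numeric, base temperature (deg C) for growing degree days
#'   (default 10, the conventional viticultural base).
#' @slot gddMethod "simple" (daily mean minus base, floored at 0) or "corn"
#'   (tmin/tmax clamped to [base, 30] before averaging).
#' @slot seasonStart,seasonEnd "MM-DD", growing season (defaults April 1 and
#'   October 31).
#' @slot freezeThreshold numeric, deg C; a freeze day has tmin <= threshold
#'   (default 0).
#' @slot coldThreshold numeric, deg C; a damaging cold day has
#'   tmin < threshold (strict; default -20).
#' @slot coldWindowStart,coldWindowEnd "MM-DD", winter window assigned to the
#'   year containing January (defaults November 1 and March 31).
#' @slot springStart,springEnd "MM-DD", spring temperature window (defaults
#'   April 1 and May 31).
#' @slot growthStart,growthEnd "MM-DD", critical-growth precipitation window
#'   (defaults April 1 and June 30).
#' @slot rotStart,rotEnd "MM-DD", veraison-to-harvest rot-risk precipitation
#'   window (defaults August 1 and October 31).
#'
#' @param gddBase,gddMethod,seasonStart,seasonEnd see slots.
#' @param freezeThreshold,coldThreshold,coldWindowStart,coldWindowEnd
#'   see slots.
#' @param springStart,springEnd,growthStart,growthEnd,rotStart,rotEnd
#'   see slots.
#' @return \code{IndexConfig()} returns a validated \code{IndexConfig}.
#' @seealso [computeAnnualIndices()]
#' @examples
#' IndexConfig()
#' IndexConfig(gddMethod = "corn", coldThreshold = -22)
#' @aliases IndexConfig
#' @export IndexConfig
#' @exportClass IndexConfig
IndexConfig <- setClass(
  "IndexConfig",
  slots = c(
    gddBase = "numeric", gddMethod = "character",
    seasonStart = "character", seasonEnd = "character",
    freezeThreshold = "numeric", coldThreshold = "numeric",
    coldWindowStart = "character", coldWindowEnd = "character",
    springStart = "character", springEnd = "character",
    growthStart = "character", growthEnd = "character",
    rotStart = "character", rotEnd = "character"
  )
)

.validMonthDay <- function(x) {
  grepl("^[01][0-9]-[0-3][0-9]$", x) &&
    !is.na(as.Date(paste0("2001-", x))) || identical(x, "02-29")
}

.monthDayNum <- function(x) {
  p <- as.integer(strsplit(x, "-", fixed = TRUE)[[1L]])
  p[1L] * 100L + p[2L]
}

setValidity("IndexConfig", function(object) {
  msg <- character()
  if (!object@gddMethod %in% c("simple", "corn")) {
    msg <- c(msg, "'gddMethod' must be \"simple\" or \"corn\"")
  }
  mds <- c(object@seasonStart, object@seasonEnd, object@coldWindowStart,
           object@coldWindowEnd, object@springStart, object@springEnd,
           object@growthStart, object@growthEnd, object@rotStart,
           object@rotEnd)
  for (md in mds) {
    if (!.validMonthDay(md)) {
      msg <- c(msg, sprintf("'%s' is not a valid MM-DD date", md))
    }
  }
  if (!length(msg)) {
    ord <- function(a, b, what) {
      if (.monthDayNum(a) > .monthDayNum(b)) {
        sprintf("window '%s' start %s is after end %s", what, a, b)
      }
    }
    msg <- c(msg,
             ord(object@seasonStart, object@seasonEnd, "season"),
             ord(object@springStart, object@springEnd, "spring"),
             ord(object@growthStart, object@growthEnd, "growth"),
             ord(object@rotStart, object@rotEnd, "rot"))
    # the cold window crosses the year boundary: start must fall after end
    if (.monthDayNum(object@coldWindowStart) <=
        .monthDayNum(object@coldWindowEnd)) {
      msg <- c(msg, "cold window must cross the year boundary (start late in the year, end early)")
    }
  }
  if (object@coldThreshold >= object@freezeThreshold) {
    msg <- c(msg, "'coldThreshold' must be below 'freezeThreshold'")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname IndexConfig-class
#' @usage NULL
IndexConfig <- function(gddBase = 10, gddMethod = "simple",
                        seasonStart = "04-01", seasonEnd = "10-31",
                        freezeThreshold = 0, coldThreshold = -20,
                        coldWindowStart = "11-01", coldWindowEnd = "03-31",
                        springStart = "04-01", springEnd = "05-31",
                        growthStart = "04-01", growthEnd = "06-30",
                        rotStart = "08-01", rotEnd = "10-31") {
  new("IndexConfig",
      gddBase = as.numeric(gddBase), gddMethod = gddMethod,
      seasonStart = seasonStart, seasonEnd = seasonEnd,
      freezeThreshold = as.numeric(freezeThreshold),
      coldThreshold = as.numeric(coldThreshold),
      coldWindowStart = coldWindowStart, coldWindowEnd = coldWindowEnd,
      springStart = springStart, springEnd = springEnd,
      growthStart = growthStart, growthEnd = growthEnd,
      rotStart = rotStart, rotEnd = rotEnd)
}

setMethod("show", "IndexConfig", function(object) {
  cat("IndexConfig\n")
  cat(sprintf("  GDD: base %.1f degC, %s method, season %s to %s\n",
              object@gddBase, object@gddMethod, object@seasonStart,
              object@seasonEnd))
  cat(sprintf("  freeze at tmin <= %.1f; cold day at tmin < %.1f (winter %s to %s)\n",
              object@freezeThreshold, object@coldThreshold,
              object@coldWindowStart, object@coldWindowEnd))
  cat(sprintf("  spring %s-%s, growth %s-%s, rot %s-%s\n",
              object@springStart, object@springEnd, object@growthStart,
              object@growthEnd, object@rotStart, object@rotEnd))
})

## -------------------------------------------------------------------------
## IndexCube
## -------------------------------------------------------------------------

#' Annual per-pixel values of one agroclimatic variable
#'
#' A year x row x col array of one index (e.g. GDD), with NA marking
#' pixel-years whose defining window was not fully observed. The unit of
#' trend analysis: each pixel's column through the cube is an annual series.
#'
#' @slot variable character, one of GDD, FCD, FFD, SPRING_T, PRECIP_GROWTH,
#'   PRECIP_ROT, GST, GS_PRECIP (free-form names allowed for custom indices).
#' @slot years integer vector, ordered calendar years.
#' @slot values numeric array (year x row x col); NA = invalid pixel-year.
#' @slot units character, physical units of the values.
#'
#' @seealso [computeAnnualIndices()], [pixelwiseTrend()]
#' @aliases IndexCube
#' @export IndexCube
#' @exportClass IndexCube
IndexCube <- setClass(
  "IndexCube",
  slots = c(variable = "character", years = "integer",
            values = "array", units = "character")
)

setValidity("IndexCube", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) {
    msg <- c(msg, "'values' must be a 3-d array (year x row x col)")
  } else if (dim(object@values)[1L] != length(object@years)) {
    msg <- c(msg, "first dimension of 'values' must match 'years'")
  }
  if (length(object@years) > 1L && any(diff(object@years) <= 0L)) {
    msg <- c(msg, "'years' must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname IndexCube-class
#' @param variable,years,values,units see slots.
#' @usage NULL
IndexCube <- function(variable, years, values, units = "") {
  new("IndexCube", variable = variable, years = as.integer(years),
      values = values, units = units)
}

#' @rdname viticlim-accessors
#' @export
setMethod("indexYears", "IndexCube", function(x) x@years)
#' @rdname viticlim-accessors
#' @export
setMethod("indexValues", "IndexCube", function(x) x@values)
#' @rdname viticlim-accessors
#' @export
setMethod("variableName", "IndexCube", function(x) x@variable)
#' @rdname viticlim-accessors
#' @export
setMethod("indexUnits", "IndexCube", function(x) x@units)
#' @rdname viticlim-accessors
#' @export
setMethod("gridShape", "IndexCube", function(x) dim(x@values)[2:3])

setMethod("show", "IndexCube", function(object) {
  d <- dim(object@values)
  nv <- sum(is.na(object@values))
  cat(sprintf("IndexCube '%s' [%s]: %d years (%d-%d), %d x %d grid, %d invalid pixel-years\n",
              object@variable, object@units, d[1L],
              object@years[1L], object@years[length(object@years)],
              d[2L], d[3L], nv))
})

## -------------------------------------------------------------------------
## TrendResult
## -------------------------------------------------------------------------

#' Result of a Mann-Kendall / Sen's slope analysis of one annual series
#'
#' @slot S numeric, integer-valued Mann-Kendall statistic: the sum over all
#'   ordered pairs of the sign of the later minus the earlier value.
#' @slot varS numeric, tie-corrected variance of S under the null.
#' @slot Z numeric, standardised statistic (continuity-corrected by default).
#' @slot pValue numeric in (0, 1], two-sided.
#' @slot tau numeric, Kendall rank correlation (tau-a by default).
#' @slot senSlope numeric, median of pairwise slopes, units per year.
#' @slot senConfInt numeric length 2, confidence interval for the slope
#'   (NA when not requested or not defined).
#' @slot alpha numeric, significance level used.
#' @slot significant logical, pValue < alpha.
#' @slot direction "increasing", "decreasing" or "none".
#' @slot n integer, series length.
#'
#' @seealso [mkTest()], [sensSlope()]
#' @aliases TrendResult
#' @exportClass TrendResult
setClass(
  "TrendResult",
  slots = c(S = "numeric", varS = "numeric", Z = "numeric",
            pValue = "numeric", tau = "numeric", senSlope = "numeric",
            senConfInt = "numeric", alpha = "numeric",
            significant = "logical", direction = "character", n = "integer")
)

setValidity("TrendResult", function(object) {
  msg <- character()
  nmax <- object@n * (object@n - 1) / 2
  if (abs(object@S) > nmax) msg <- c(msg, "S out of range for n")
  if (object@varS < 0) msg <- c(msg, "varS must be >= 0")
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1)) {
    msg <- c(msg, "pValue must lie in (0, 1]")
  }
  if (!object@direction %in% c("increasing", "decreasing", "none")) {
    msg <- c(msg, "invalid direction")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrendResult", function(object) {
  cat("Mann-Kendall trend test\n")
  cat(sprintf("  n = %d, S = %d, var(S) = %.3f, Z = %.3f\n",
              object@n, as.integer(object@S), object@varS, object@Z))
  cat(sprintf("  tau = %.3f, two-sided p = %.4g (alpha = %.2f)\n",
              object@tau, object@pValue, object@alpha))
  ci <- if (all(is.na(object@senConfInt))) "" else
    sprintf(" [%.4g, %.4g]", object@senConfInt[1L], object@senConfInt[2L])
  cat(sprintf("  Sen's slope = %.4g%s per year; trend: %s%s\n",
              object@senSlope, ci, object@direction,
              if (object@significant) " (significant)" else ""))
})

#' @rdname viticlim-accessors
#' @export
setMethod("alphaLevel", "TrendResult", function(x) x@alpha)

## -------------------------------------------------------------------------
## TrendRaster
## -------------------------------------------------------------------------

#' Per-pixel trend layers for one variable and one analysis window
#'
#' Pixel-wise Mann-Kendall and Sen's slope results: slope, Kendall tau and
#' p-value layers plus logical significance and validity masks. In the slope
#' layer, pixels that are invalid or not significant carry NA (never 0), so a
#' map of the layer reproduces the "white = no significant change"
#' convention; the full, unmasked slopes remain available for re-thresholding
#' via \code{slopeLayer(x, masked = FALSE)}.
#'
#' @slot variable character, index name.
#' @slot window character, window label (e.g. "1983-2019").
#' @slot startYear,endYear integer, inclusive window bounds.
#' @slot slope,tau,pValue numeric row x col matrices (NA where invalid).
#' @slot significant,valid logical row x col matrices.
#' @slot alpha numeric, significance level used.
#'
#' @seealso [pixelwiseTrend()], [changedAreaProportion()]
#' @aliases TrendRaster
#' @exportClass TrendRaster
setClass(
  "TrendRaster",
  slots = c(variable = "character", window = "character",
            startYear = "integer", endYear = "integer",
            slope = "matrix", tau = "matrix", pValue = "matrix",
            significant = "matrix", valid = "matrix", alpha = "numeric")
)

setValidity("TrendRaster", function(object) {
  msg <- character()
  d <- dim(object@slope)
  for (nm in c("tau", "pValue", "significant", "valid")) {
    if (!identical(dim(slot(object, nm)), d)) {
      msg <- c(msg, sprintf("layer '%s' dimensions differ from 'slope'", nm))
    }
  }
  if (!is.logical(object@significant) || !is.logical(object@valid)) {
    msg <- c(msg, "'significant' and 'valid' must be logical matrices")
  } else {
    if (any(object@significant & !object@valid, na.rm = TRUE)) {
      msg <- c(msg, "significant pixels must be valid")
    }
  }
  if (object@alpha <= 0 || object@alpha >= 1) {
    msg <- c(msg, "'alpha' must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname viticlim-accessors
#' @param masked logical; for \code{slopeLayer}, mask non-significant pixels
#'   to NA (the mapping convention) or return all valid-pixel slopes.
#' @export
setMethod("slopeLayer", "TrendRaster", function(x, masked = TRUE) {
  if (masked) {
    out <- x@slope
    out[!x@significant | !x@valid] <- NA_real_
    out
  } else {
    x@slope
  }
})

#' @rdname viticlim-accessors
#' @export
setMethod("tauLayer", "TrendRaster", function(x) x@tau)
#' @rdname viticlim-accessors
#' @export
setMethod("pValueLayer", "TrendRaster", function(x) x@pValue)
#' @rdname viticlim-accessors
#' @export
setMethod("significanceMask", "TrendRaster", function(x) x@significant)
#' @rdname viticlim-accessors
#' @export
setMethod("validityMask", "TrendRaster", function(x) x@valid)
#' @rdname viticlim-accessors
#' @export
setMethod("alphaLevel", "TrendRaster", function(x) x@alpha)
#' @rdname viticlim-accessors
#' @export
setMethod("gridShape", "TrendRaster", function(x) dim(x@slope))
#' @rdname viticlim-accessors
#' @export
setMethod("variableName", "TrendRaster", function(x) x@variable)

setMethod("show", "TrendRaster", function(object) {
  d <- dim(object@slope)
  nsig <- sum(object@significant & object@valid, na.rm = TRUE)
  nval <- sum(object@valid, na.rm = TRUE)
  cat(sprintf("TrendRaster '%s', window %s (alpha %.2f)\n",
              object@variable, object@window, object@alpha))
  cat(sprintf("  %d x %d grid, %d valid pixels, %d significant (%.1f%%)\n",
              d[1L], d[2L], nval, nsig,
              if (nval > 0) 100 * nsig / nval else NA_real_))
})
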