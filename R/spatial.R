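#' @include AllClasses.R
NULL

# the nine standard analysis windows for a 1983-2019 record: the full span,
# first/last 20, thirds (12/12/13), first/last 30, and the last 8 years
.defaultWindowSpans <- function() {
  list(c(1983L, 2019L), c(1983L, 2002L), c(2000L, 2019L),
       c(1983L, 1994L), c(1995L, 2006L), c(2007L, 2019L),
       c(1983L, 2012L), c(1990L, 2019L), c(2012L, 2019L))
}

#' Build the set of analysis windows
#'
#' With no arguments, returns the nine standard inclusive year spans used
#' for a 37-year 1983-2019 record: the entire period, the first and last
#' 20 years, three consecutive sub-periods of 12/12/13 years, the first and
#' last 30 years, and the last 8 years. A custom list of c(start, end)
#' spans may be supplied instead; each must contain at least 3 years and,
#' when \code{dataYears} is given, fall inside the data's year range.
#'
#' @param spans optional list of length-2 integer vectors c(start, end).
#' @param dataYears optional integer vector of available years used to
#'   validate coverage.
#' @return data.frame with columns label, start_year, end_year, n_years.
#' @examples
#' buildWindows()
#' buildWindows(list(c(1990, 2005)))
#' @export
buildWindows <- function(spans = NULL, dataYears = NULL) {
  if (is.null(spans)) spans <- .defaultWindowSpans()
  out <- do.call(rbind, lapply(spans, function(sp) {
    if (length(sp) != 2L || anyNA(sp)) {
      stop("each window span must be c(start_year, end_year)", call. = FALSE)
    }
    sp <- as.integer(sp)
    if (sp[1L] > sp[2L]) {
      stop(sprintf("window %d-%d has start after end", sp[1L], sp[2L]),
           call. = FALSE)
    }
    n <- sp[2L] - sp[1L] + 1L
    if (n < 3L) {
      stop(sprintf("window %d-%d spans %d year(s); at least 3 are required for a trend test",
                   sp[1L], sp[2L], n), call. = FALSE)
    }
    if (!is.null(dataYears) &&
        (sp[1L] < min(dataYears) || sp[2L] > max(dataYears))) {
      stop(sprintf("window %d-%d lies outside the data years %d-%d",
                   sp[1L], sp[2L], min(dataYears), max(dataYears)),
           call. = FALSE)
    }
    data.frame(label = sprintf("%d-%d", sp[1L], sp[2L]),
               start_year = sp[1L], end_year = sp[2L], n_years = n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-pixel trend analysis of one index cube over one window
#'
#' Extracts each pixel's annual series for the window's inclusive year span
#' and runs the Mann-Kendall test and Sen's slope estimator ([mkTest()]) on
#' it. A pixel is invalid when any year of the window is missing for it;
#' invalid pixels carry NA in every layer. Significance is assessed per
#' pixel at \code{alpha} with no multiple-testing adjustment across pixels,
#' matching the usual climate trend-mapping convention.
#'
#' @param cube an [IndexCube-class].
#' @param window one row of [buildWindows()] output (or any list with
#'   label, start_year, end_year).
#' @param alpha per-pixel significance level, default 0.10.
#' @param ... further arguments passed to [mkTest()].
#' @return A [TrendRaster-class].
#' @examples
#' g <- generateDailyClimate(GeneratorConfig(nYears = 10, startYear = 2000,
#'                                           nRows = 3, nCols = 3,
#'                                           tTrend = 0.3, seed = 5))
#' gst <- computeAnnualIndices(g)$GST
#' pixelwiseTrend(gst, list(label = "2000-2009", start_year = 2000,
#'                          end_year = 2009))
#' @export
pixelwiseTrend <- function(cube, window, alpha = 0.10, ...) {
  if (!is(cube, "IndexCube")) stop("'cube' must be an IndexCube",
                                   call. = FALSE)
  ys <- as.integer(window$start_year)
  ye <- as.integer(window$end_year)
  sel <- which(cube@years >= ys & cube@years <= ye)
  if (length(sel) != ye - ys + 1L) {
    stop(sprintf("cube years do not cover window %d-%d", ys, ye),
         call. = FALSE)
  }
  yrs <- cube@years[sel]
  vals <- cube@values[sel, , , drop = FALSE]
  d <- dim(vals)[2:3]
  slope <- tau <- pval <- matrix(NA_real_, d[1L], d[2L])
  sig <- valid <- matrix(FALSE, d[1L], d[2L])
  for (r in seq_len(d[1L])) {
    for (cc in seq_len(d[2L])) {
      x <- vals[, r, cc]
      if (anyNA(x)) next
      valid[r, cc] <- TRUE
      res <- mkTest(x, years = yrs, alpha = alpha, ...)
      slope[r, cc] <- res@senSlope
      tau[r, cc] <- res@tau
      pval[r, cc] <- res@pValue
      sig[r, cc] <- res@significant
    }
  }
  new("TrendRaster", variable = cube@variable,
      window = sprintf("%s", window$label),
      startYear = ys, endYear = ye,
      slope = slope, tau = tau, pValue = pval,
      significant = sig, valid = valid, alpha = alpha)
}

#' Proportion of area with a significant trend
#'
#' The fraction of valid pixels whose per-pixel test is significant; the
#' denominator is the count of valid pixels (pixels with a complete series
#' in the window). With \code{bySign = TRUE} the significant fraction is
#' split by the sign of the Sen's slope; the two parts sum to the total.
#'
#' @param raster a [TrendRaster-class] with at least one valid pixel.
#' @param bySign logical, split by trend direction.
#' @return A single fraction in [0, 1], or (with \code{bySign}) a named
#'   numeric c(total, increasing, decreasing).
#' @export
changedAreaProportion <- function(raster, bySign = FALSE) {
  stopifnot(is(raster, "TrendRaster"))
  nValid <- sum(raster@valid)
  if (nValid == 0L) {
    stop("no valid pixels: changed-area proportion undefined", call. = FALSE)
  }
  sig <- raster@significant & raster@valid
  total <- sum(sig) / nValid
  if (!bySign) return(total)
  up <- sum(sig & raster@slope > 0, na.rm = TRUE) / nValid
  down <- sum(sig & raster@slope < 0, na.rm = TRUE) / nValid
  c(total = total, increasing = up, decreasing = down)
}

#' Variable-by-window trend summary table
#'
#' Runs [pixelwiseTrend()] for every combination of index cube and analysis
#' window and tabulates, per combination: valid and significant pixel
#' counts, the changed-area proportion (total and split by sign), and the
#' minimum / median / maximum Sen's slope among significant pixels. With the
#' eight standard variables and the nine standard windows the table has 72
#' rows. A combination with no valid pixel (e.g. a winter-defined variable
#' in a window touching the record's first year) carries NA proportions.
#'
#' @param cubes named list of [IndexCube-class] objects on a common year
#'   axis.
#' @param windows data.frame from [buildWindows()].
#' @param alpha per-pixel significance level, default 0.10.
#' @param ... passed to [mkTest()].
#' @return data.frame, one row per variable x window.
#' @export
summarizeTrends <- function(cubes, windows = buildWindows(), alpha = 0.10,
                            ...) {
  rows <- list()
  for (v in names(cubes)) {
    for (i in seq_len(nrow(windows))) {
      w <- windows[i, ]
      tr <- pixelwiseTrend(cubes[[v]], w, alpha = alpha, ...)
      sig <- tr@significant & tr@valid
      sl <- tr@slope[sig]
      # a cube can have no valid pixel in a window (e.g. the first-year
      # winter gap makes FCD undefined in any window touching year 1)
      prop <- if (any(tr@valid)) changedAreaProportion(tr, bySign = TRUE)
      else c(total = NA_real_, increasing = NA_real_,
             decreasing = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, window = w$label,
        n_years = w$n_years,
        n_valid = sum(tr@valid), n_significant = sum(sig),
        prop_changed = prop[["total"]],
        prop_increasing = prop[["increasing"]],
        prop_decreasing = prop[["decreasing"]],
        slope_min = if (length(sl)) min(sl) else NA_real_,
        slope_median = if (length(sl)) stats::median(sl) else NA_real_,
        slope_max = if (length(sl)) max(sl) else NA_real_,
        alpha = alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
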