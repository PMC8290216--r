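#' @include AllClasses.R
NULL

## Grid serialization --------------------------------------------------------
## Self-describing plain-text container: a '#'-prefixed YAML header carrying
## the dimensions, units, start date and grid-spacing attributes, followed by
## a long-format CSV table. Intended for desk-scale grids; the header makes
## the files portable without side-car metadata.

.writeHeaderedCsv <- function(df, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", strsplit(yaml::as.yaml(header), "\n")[[1L]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.readHeaderedCsv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  nHdr <- match(FALSE, hdr) - 1L
  meta <- yaml::yaml.load(paste(sub("^# ", "", lines[seq_len(nHdr)]),
                                collapse = "\n"))
  df <- utils::read.csv(text = lines[-seq_len(nHdr)])
  list(meta = meta, data = df)
}

#' Write / read a ClimateGrid as a self-describing text file
#'
#' The on-disk form is a YAML header (format tag, dimensions, variable
#' units, start year, grid origin and spacing) above a long CSV table with
#' columns date, row, col, tmin, tmax, precip. \code{readClimateGrid}
#' inverts it exactly.
#'
#' @param grid a [ClimateGrid-class].
#' @param path file path.
#' @return \code{writeClimateGrid} returns \code{path} invisibly;
#'   \code{readClimateGrid} returns a [ClimateGrid-class].
#' @examples
#' g <- generateDailyClimate(GeneratorConfig(nYears = 3, nRows = 2,
#'                                           nCols = 2, seed = 2))
#' f <- tempfile(fileext = ".csv")
#' writeClimateGrid(g, f)
#' g2 <- readClimateGrid(f)
#' identical(climTmin(g), climTmin(g2))
#' @export
writeClimateGrid <- function(grid, path) {
  stopifnot(is(grid, "ClimateGrid"))
  d <- dim(grid@tmin)
  header <- list(
    format = "viticlim-climate-grid", version = 1L,
    n_time = d[1L], n_rows = d[2L], n_cols = d[3L],
    start_date = format(grid@dates[1L]),
    units = list(tmin = "degC", tmax = "degC", precip = "mm"),
    origin = as.numeric(grid@origin), spacing = as.numeric(grid@spacing))
  idx <- expand.grid(t = seq_len(d[1L]), row = seq_len(d[2L]),
                     col = seq_len(d[3L]))
  df <- data.frame(date = format(grid@dates[idx$t]), row = idx$row,
                   col = idx$col,
                   tmin = as.vector(grid@tmin), tmax = as.vector(grid@tmax),
                   precip = as.vector(grid@precip))
  .writeHeaderedCsv(df, header, path)
  invisible(path)
}

#' @rdname writeClimateGrid
#' @export
readClimateGrid <- function(path) {
  imp <- .readHeaderedCsv(path)
  .gridFromTable(imp$data, imp$meta,
                 variableMap = c(tmin = "tmin", tmax = "tmax",
                                 precip = "precip"))
}

# assemble a ClimateGrid from a long table with date/row/col + mapped
# variable columns; errors list every defect found
.gridFromTable <- function(df, meta, variableMap,
                           units = c(temperature = "degC",
                                     precipitation = "mm")) {
  defects <- character()
  for (v in c("tmin", "tmax", "precip")) {
    if (!variableMap[[v]] %in% names(df)) {
      defects <- c(defects, sprintf("missing variable '%s' (column '%s')",
                                    v, variableMap[[v]]))
    }
  }
  for (v in c("date", "row", "col")) {
    if (!v %in% names(df)) {
      defects <- c(defects, sprintf("missing column '%s'", v))
    }
  }
  if (length(defects)) {
    stop("import failed: ", paste(defects, collapse = "; "), call. = FALSE)
  }

  tconv <- switch(units[["temperature"]],
                  degC = identity,
                  degF = function(x) (x - 32) / 1.8,
                  NULL)
  pconv <- switch(units[["precipitation"]],
                  mm = identity,
                  inches = , "in" = function(x) x * 25.4,
                  cm = function(x) x * 10,
                  NULL)
  if (is.null(tconv)) defects <- c(defects, sprintf(
    "unknown temperature unit '%s' (degC or degF)", units[["temperature"]]))
  if (is.null(pconv)) defects <- c(defects, sprintf(
    "unknown precipitation unit '%s' (mm, cm or inches)",
    units[["precipitation"]]))
  if (length(defects)) {
    stop("import failed: ", paste(defects, collapse = "; "), call. = FALSE)
  }

  dates <- sort(unique(as.Date(df$date)))
  if (length(dates) > 1L && !all(diff(as.integer(dates)) == 1L)) {
    stop("import failed: calendar has gaps (non-consecutive dates)",
         call. = FALSE)
  }
  nR <- max(df$row)
  nC <- max(df$col)
  nT <- length(dates)
  shape <- c(nT, nR, nC)
  fill <- function(col, conv) {
    arr <- array(NA_real_, shape)
    ti <- match(as.Date(df$date), dates)
    arr[cbind(ti, df$row, df$col)] <- conv(df[[col]])
    arr
  }
  ClimateGrid(dates = dates,
              tmin = fill(variableMap[["tmin"]], tconv),
              tmax = fill(variableMap[["tmax"]], tconv),
              precip = fill(variableMap[["precip"]], pconv),
              origin = if (!is.null(meta$origin)) meta$origin else c(0, 0),
              spacing = if (!is.null(meta$spacing)) meta$spacing else c(1, 1))
}

#' Import an external daily climate table as a ClimateGrid
#'
#' Adapter for pre-downloaded gridded daily records exported to the headered
#' CSV layout (see [writeClimateGrid()]), with arbitrary column names and
#' declared units. Temperatures are normalised to deg C and precipitation to
#' mm on import. Defects (missing variables, unknown units, calendar gaps)
#' are reported together in the error message.
#'
#' @param path file path.
#' @param variableMap named character vector mapping tmin/tmax/precip to
#'   column names in the file.
#' @param units named character vector with entries \code{temperature}
#'   ("degC" or "degF") and \code{precipitation} ("mm", "cm" or "inches").
#' @return A validated [ClimateGrid-class] in deg C / mm.
#' @export
importExternalGrid <- function(path,
                               variableMap = c(tmin = "tmin", tmax = "tmax",
                                               precip = "precip"),
                               units = c(temperature = "degC",
                                         precipitation = "mm")) {
  imp <- .readHeaderedCsv(path)
  .gridFromTable(imp$data, imp$meta, variableMap, units)
}

#' Write an IndexCube or TrendRaster as headered text
#'
#' IndexCubes go to a tidy CSV (year, row, col, value) under a YAML header
#' carrying the variable name and units. TrendRasters go to a tidy CSV
#' (row, col, slope, tau, p_value, significant, valid) under a header with
#' the variable, window and alpha; non-significant pixels keep their slope
#' in the table (the significance column is the mask) while
#' [slopeLayer()] applies the masked view in memory.
#'
#' @param x an [IndexCube-class] or [TrendRaster-class].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeIndexCube <- function(x, path) {
  stopifnot(is(x, "IndexCube"))
  d <- dim(x@values)
  header <- list(format = "viticlim-index-cube", version = 1L,
                 variable = x@variable, units = x@units,
                 years = as.integer(x@years),
                 n_rows = d[2L], n_cols = d[3L])
  idx <- expand.grid(y = seq_len(d[1L]), row = seq_len(d[2L]),
                     col = seq_len(d[3L]))
  df <- data.frame(year = x@years[idx$y], row = idx$row, col = idx$col,
                   value = as.vector(x@values))
  .writeHeaderedCsv(df, header, path)
  invisible(path)
}

#' @rdname writeIndexCube
#' @export
readIndexCube <- function(path) {
  imp <- .readHeaderedCsv(path)
  yrs <- sort(unique(imp$data$year))
  arr <- array(NA_real_, c(length(yrs), imp$meta$n_rows, imp$meta$n_cols))
  arr[cbind(match(imp$data$year, yrs), imp$data$row, imp$data$col)] <-
    imp$data$value
  IndexCube(imp$meta$variable, yrs, arr, units = imp$meta$units)
}

#' @rdname writeIndexCube
#' @export
writeTrendRaster <- function(x, path) {
  stopifnot(is(x, "TrendRaster"))
  d <- dim(x@slope)
  header <- list(format = "viticlim-trend-raster", version = 1L,
                 variable = x@variable, window = x@window,
                 start_year = x@startYear, end_year = x@endYear,
                 alpha = x@alpha, n_rows = d[1L], n_cols = d[2L])
  idx <- expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L]))
  df <- data.frame(row = idx$row, col = idx$col,
                   slope = as.vector(x@slope), tau = as.vector(x@tau),
                   p_value = as.vector(x@pValue),
                   significant = as.vector(x@significant),
                   valid = as.vector(x@valid))
  .writeHeaderedCsv(df, header, path)
  invisible(path)
}
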