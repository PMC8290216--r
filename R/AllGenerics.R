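#' @include AllGenerics.R
NULL

#' Accessor generics for viticlim classes
#'
#' Small family of accessors used across the package's S4 classes:
#' \code{climDates}, \code{climTmin}, \code{climTmax}, \code{climPrecip} for
#' [ClimateGrid-class]; \code{indexYears}, \code{indexValues},
#' \code{variableName}, \code{indexUnits} for [IndexCube-class];
#' \code{slopeLayer}, \code{tauLayer}, \code{pValueLayer},
#' \code{significanceMask}, \code{validityMask}, \code{alphaLevel} for
#' [TrendRaster-class]; \code{gridShape} for both grid-like classes.
#'
#' @param x an object of the relevant viticlim class.
#' @return The slot contents: a \code{Date} vector, numeric array/matrix,
#'   character scalar, integer vector, logical matrix or numeric scalar
#'   depending on the accessor.
#' @name viticlim-accessors
#' @examples
#' cfg <- GeneratorConfig(nYears = 3, nRows = 2, nCols = 2, seed = 1)
#' g <- generateDailyClimate(cfg)
#' head(climDates(g))
#' gridShape(g)
NULL

#' @rdname viticlim-accessors
#' @export
setGeneric("climDates", function(x) standardGeneric("climDates"))

#' @rdname viticlim-accessors
#' @export
setGeneric("climTmin", function(x) standardGeneric("climTmin"))

#' @rdname viticlim-accessors
#' @export
setGeneric("climTmax", function(x) standardGeneric("climTmax"))

#' @rdname viticlim-accessors
#' @export
setGeneric("climPrecip", function(x) standardGeneric("climPrecip"))

#' @rdname viticlim-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname viticlim-accessors
#' @export
setGeneric("indexYears", function(x) standardGeneric("indexYears"))

#' @rdname viticlim-accessors
#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))

#' @rdname viticlim-accessors
#' @export
setGeneric("variableName", function(x) standardGeneric("variableName"))

#' @rdname viticlim-accessors
#' @export
setGeneric("indexUnits", function(x) standardGeneric("indexUnits"))

#' @rdname viticlim-accessors
#' @export
setGeneric("slopeLayer", function(x, ...) standardGeneric("slopeLayer"))

#' @rdname viticlim-accessors
#' @export
setGeneric("tauLayer", function(x) standardGeneric("tauLayer"))

#' @rdname viticlim-accessors
#' @export
setGeneric("pValueLayer", function(x) standardGeneric("pValueLayer"))

#' @rdname viticlim-accessors
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname viticlim-accessors
#' @export
setGeneric("validityMask", function(x) standardGeneric("validityMask"))

#' @rdname viticlim-accessors
#' @export
setGeneric("alphaLevel", function(x) standardGeneric("alphaLevel"))
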