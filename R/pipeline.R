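#' @include AllClasses.R
NULL

#' End-to-end pipeline configuration
#'
#' Bundles everything a full run needs: the significance level, the seed,
#' optional input/output paths, the index definitions, the generator
#' settings (used when no climate input path is given) and the analysis
#' window spans. An empty configuration file yields exactly this object's
#' defaults: alpha 0.10, the nine standard windows, default
#' [IndexConfig-class] and [GeneratorConfig-class].
#'
#' @slot alpha numeric in (0, 1), per-pixel significance level.
#' @slot seed integer; overrides the generator seed when simulating.
#' @slot climatePath character, path to an importable climate file, or ""
#'   to simulate.
#' @slot outDir character, output directory ("" = no files written).
#' @slot windows NULL (the nine standard spans) or a list of c(start, end).
#' @slot indexConfig an [IndexConfig-class].
#' @slot generatorConfig a [GeneratorConfig-class].
#' @slot logLevel "info" or "quiet".
#'
#' @param alpha,seed,climatePath,outDir,windows,indexConfig,generatorConfig
#'   see slots.
#' @param logLevel see slots.
#' @return \code{PipelineConfig()} returns a validated object.
#' @seealso [loadConfig()], [runPipeline()]
#' @aliases PipelineConfig
#' @export PipelineConfig
#' @exportClass PipelineConfig
PipelineConfig <- setClass(
  "PipelineConfig",
  slots = c(alpha = "numeric", seed = "integer", climatePath = "character",
            outDir = "character", windows = "ANY",
            indexConfig = "IndexConfig", generatorConfig = "GeneratorConfig",
            logLevel = "character")
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 1) {
    msg <- c(msg, "'alpha' must lie in (0, 1)")
  }
  if (!object@logLevel %in% c("info", "quiet")) {
    msg <- c(msg, "'logLevel' must be \"info\" or \"quiet\"")
  }
  if (!is.null(object@windows) && !is.list(object@windows)) {
    msg <- c(msg, "'windows' must be NULL or a list of c(start, end) spans")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PipelineConfig-class
#' @usage NULL
PipelineConfig <- function(alpha = 0.10, seed = 1L, climatePath = "",
                           outDir = "", windows = NULL,
                           indexConfig = IndexConfig(),
                           generatorConfig = GeneratorConfig(),
                           logLevel = "info") {
  new("PipelineConfig", alpha = as.numeric(alpha), seed = as.integer(seed),
      climatePath = climatePath, outDir = outDir, windows = windows,
      indexConfig = indexConfig, generatorConfig = generatorConfig,
      logLevel = logLevel)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  alpha %.2f, seed %d, input: %s\n", object@alpha,
              object@seed,
              if (nzchar(object@climatePath)) object@climatePath else
                "(simulate)"))
  nw <- if (is.null(object@windows)) 9L else length(object@windows)
  cat(sprintf("  %d analysis windows, log level %s\n", nw, object@logLevel))
})

## configuration file keys, mapped 1:1 onto constructor arguments
.configKeys <- list(
  top = c("alpha", "seed", "climate", "out", "windows", "index",
          "generator", "log_level"),
  index = c("gddBase", "gddMethod", "seasonStart", "seasonEnd",
            "freezeThreshold", "coldThreshold", "coldWindowStart",
            "coldWindowEnd", "springStart", "springEnd", "growthStart",
            "growthEnd", "rotStart", "rotEnd"),
  generator = c("nYears", "startYear", "nRows", "nCols", "meanAnnualT",
                "seasonalAmplitude", "diurnalRange", "nsGradient",
                "ar1Coeff", "dailyNoiseSd", "tTrend", "wetProbByMonth",
                "precipShape", "precipScale", "pTrend", "wetPersistence",
                "seed")
)

.checkKeys <- function(given, allowed, section) {
  bad <- setdiff(names(given), allowed)
  if (length(bad)) {
    stop(sprintf("unknown configuration key%s in %s: %s (allowed: %s)",
                 if (length(bad) > 1L) "s" else "", section,
                 paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
}

#' Load / save a pipeline configuration file
#'
#' The configuration format is YAML with top-level keys \code{alpha},
#' \code{seed}, \code{climate}, \code{out}, \code{windows} (list of
#' two-element year spans), \code{index} (see [IndexConfig()] arguments),
#' \code{generator} (see [GeneratorConfig()] arguments) and
#' \code{log_level}. Every key is optional; an empty file gives the full
#' default configuration. Unknown keys are rejected by name.
#' \code{saveConfig} writes a file that \code{loadConfig} restores to an
#' equal object (per-pixel trend matrices are not serialisable).
#'
#' @param path configuration file path.
#' @return \code{loadConfig}: a validated [PipelineConfig-class];
#'   \code{saveConfig}: \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("alpha: 0.05", f)
#' loadConfig(f)
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .checkKeys(raw, .configKeys$top, "the top level")
  if (!is.null(raw$index)) .checkKeys(raw$index, .configKeys$index, "'index'")
  if (!is.null(raw$generator)) {
    .checkKeys(raw$generator, .configKeys$generator, "'generator'")
  }
  if (!is.null(raw$alpha) && (raw$alpha <= 0 || raw$alpha >= 1)) {
    stop("configuration key 'alpha' must lie in (0, 1), got ", raw$alpha,
         call. = FALSE)
  }
  windows <- if (is.null(raw$windows)) NULL else
    lapply(raw$windows, function(w) as.integer(unlist(w)))
  PipelineConfig(
    alpha = if (is.null(raw$alpha)) 0.10 else raw$alpha,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    climatePath = if (is.null(raw$climate)) "" else raw$climate,
    outDir = if (is.null(raw$out)) "" else raw$out,
    windows = windows,
    indexConfig = do.call(IndexConfig,
                          if (is.null(raw$index)) list() else raw$index),
    generatorConfig = do.call(GeneratorConfig,
                              if (is.null(raw$generator)) list() else
                                raw$generator),
    logLevel = if (is.null(raw$log_level)) "info" else raw$log_level)
}

#' @rdname loadConfig
#' @param config a [PipelineConfig-class].
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  gc_ <- config@generatorConfig
  if (is.matrix(gc_@tTrend) || is.matrix(gc_@pTrend)) {
    stop("per-pixel trend fields cannot be serialised to a config file",
         call. = FALSE)
  }
  ic <- config@indexConfig
  out <- list(
    alpha = config@alpha, seed = config@seed,
    climate = config@climatePath, out = config@outDir,
    windows = if (is.null(config@windows)) NULL else
      lapply(config@windows, as.integer),
    index = stats::setNames(
      lapply(.configKeys$index, function(k) slot(ic, k)),
      .configKeys$index),
    generator = stats::setNames(
      lapply(.configKeys$generator, function(k) slot(gc_, k)),
      .configKeys$generator),
    log_level = config@logLevel)
  out <- out[!vapply(out, is.null, logical(1L))]
  yaml::write_yaml(out, path)
  invisible(path)
}

.logStage <- function(config, fmt, ...) {
  if (config@logLevel != "quiet") message(sprintf(fmt, ...))
}

#' Run the full trend-analysis pipeline
#'
#' Executes climate acquisition (import, or simulation when no input path
#' is configured), annual index computation, window construction, per-pixel
#' trend testing for every variable x window, and the changed-area summary
#' table. When an output directory is configured, writes the eight index
#' cubes, all trend rasters, the summary CSV, the resolved configuration
#' and a machine-readable provenance record (config file hash, seed,
#' package and R versions) sufficient to reproduce the run bit-identically.
#'
#' @param config a [PipelineConfig-class] (default: all defaults, i.e. a
#'   simulated 37-year 20 x 20 record analysed over the nine standard
#'   windows).
#' @return Invisibly, a list with elements \code{grid}, \code{cubes},
#'   \code{windows}, \code{rasters} (list of [TrendRaster-class]),
#'   \code{summary} (data.frame).
#' @examples
#' cfg <- PipelineConfig(generatorConfig = GeneratorConfig(
#'   nYears = 10, startYear = 2000, nRows = 3, nCols = 3, seed = 4),
#'   windows = list(c(2000, 2009)), logLevel = "quiet")
#' res <- runPipeline(cfg)
#' head(res$summary)
#' @export
runPipeline <- function(config = PipelineConfig()) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)

  if (nzchar(config@climatePath)) {
    grid <- importExternalGrid(config@climatePath)
    .logStage(config, "imported climate: %d days, %d x %d grid",
              length(grid@dates), gridShape(grid)[1L], gridShape(grid)[2L])
  } else {
    genCfg <- config@generatorConfig
    genCfg@seed <- config@seed
    grid <- generateDailyClimate(genCfg)
    .logStage(config, "simulated climate: %d days, %d x %d grid, seed %d",
              length(grid@dates), gridShape(grid)[1L], gridShape(grid)[2L],
              config@seed)
  }

  cubes <- computeAnnualIndices(grid, config@indexConfig)
  for (v in names(cubes)) {
    nv <- sum(!is.na(cubes[[v]]@values))
    .logStage(config, "index %s: %d valid pixel-years", v, nv)
  }

  windows <- buildWindows(config@windows, dataYears = cubes[[1L]]@years)
  .logStage(config, "%d analysis windows", nrow(windows))

  rasters <- list()
  for (v in names(cubes)) {
    for (i in seq_len(nrow(windows))) {
      tr <- pixelwiseTrend(cubes[[v]], windows[i, ], alpha = config@alpha)
      rasters[[sprintf("%s_%s", v, windows$label[i])]] <- tr
    }
  }
  summary <- summarizeTrends(cubes, windows, alpha = config@alpha)
  .logStage(config, "summary: %d variable-window rows", nrow(summary))

  if (nzchar(config@outDir)) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    for (v in names(cubes)) {
      writeIndexCube(cubes[[v]], file.path(config@outDir,
                                           sprintf("index_%s.csv", v)))
    }
    for (nm in names(rasters)) {
      writeTrendRaster(rasters[[nm]],
                       file.path(config@outDir,
                                 sprintf("trend_%s.csv", nm)))
    }
    utils::write.csv(summary, file.path(config@outDir, "summary.csv"),
                     row.names = FALSE)
    cfgPath <- file.path(config@outDir, "config.yaml")
    cfgSerializable <- !is.matrix(config@generatorConfig@tTrend) &&
      !is.matrix(config@generatorConfig@pTrend)
    if (cfgSerializable) saveConfig(config, cfgPath)
    prov <- list(
      package = "viticlim",
      package_version = as.character(utils::packageVersion("viticlim")),
      r_version = as.character(getRversion()),
      seed = config@seed, alpha = config@alpha,
      config_md5 = if (cfgSerializable)
        unname(tools::md5sum(cfgPath)) else NA,
      simulated = !nzchar(config@climatePath),
      n_windows = nrow(windows), n_variables = length(cubes))
    jsonlite::write_json(prov, file.path(config@outDir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .logStage(config, "outputs written to %s", config@outDir)
  }

  invisible(list(grid = grid, cubes = cubes, windows = windows,
                 rasters = rasters, summary = summary))
}
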