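Package: viticlim
Title: Agroclimatic Indices and Pixel-Wise Trend Detection for Cool-Climate Viticulture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes viticulture-relevant agroclimatic indices (growing degree
    days at base 10 degrees C, frost-free season length, frequency of damaging
    cold days, windowed precipitation totals and temperature means) from
    gridded daily climate, and detects per-pixel monotonic trends over multiple
    analysis windows with a from-scratch Mann-Kendall test (tie-corrected
    normal approximation, optional exact small-sample mode) and the Sen's
    slope estimator. Produces significance-masked slope rasters and
    changed-area summaries. Includes a stochastic daily weather generator with
    injectable warming and precipitation trends so the full pipeline can be
    validated by parameter recovery without any external climate download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'indices.R'
    'io.R'
    'pipeline.R'
    'spatial.R'
    'synthetic.R'
    'trend.R'
    'viticlim-package.R'
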