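---
title: "Methods: trend detection in viticultural agroclimate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend detection in viticultural agroclimate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viticlim)
```

## Overview

`viticlim` maps where and how fast the climate variables that govern
cool-climate wine-grape production are changing. The pipeline has three
stages: daily gridded climate (simulated or imported), annual agroclimatic
indices per pixel, and per-pixel nonparametric trend tests over a set of
analysis windows. This vignette documents the statistical model, the
conventions and defaults, the numerical edge cases, and what the synthetic
validation does and does not demonstrate.

## The trend model

Each pixel contributes one annual series per variable. We test for a
monotonic trend with the Mann-Kendall statistic

$$S = \sum_{k=1}^{n-1}\sum_{j=k+1}^{n}\operatorname{sign}(x_j - x_k),$$

a rank statistic that makes no distributional assumption — the reason it is
the standard choice for skewed, bounded and count-valued climate indices.
Its null variance uses the tie correction

$$\operatorname{var}(S)=\tfrac{1}{18}\Big[n(n-1)(2n+5)-\sum_g t_g(t_g-1)(2t_g+5)\Big],$$

which matters in practice: FCD series are mostly small integers and tie
heavily. Significance uses the continuity-corrected normal deviate
$Z=(S-\operatorname{sign}(S))/\sqrt{\operatorname{var}(S)}$, two-sided,
because both warming and cooling (or wetting and drying) trends are of
interest. The magnitude estimate is Sen's slope, the median of all
$\binom{n}{2}$ pairwise slopes in physical units per year, robust to
outliers such as a single extreme vintage.

Conventions that the literature leaves open, and how they are fixed here:

* **Continuity and tie corrections** are both on by default; either can be
  switched off (`continuity = FALSE`, `tieCorrection = FALSE`). For
  $n \le 10$ tie-free series `method = "exact"` replaces the normal
  approximation with the exact permutation null of $S$, computed by the
  inversion-count convolution.
* **A fully tied series** is a defined degenerate result
  ($S = 0$, $Z = 0$, $p = 1$, no trend), never an exception: masked
  rasters must not fail on a constant pixel.
* **Kendall's τ** is reported as τ-a $= S / \binom{n}{2}$ by default, with
  the tie-adjusted τ-b available (`tauMethod = "b"`); slope maps are always
  in physical units per year, with the τ layer carried alongside.
* **No pre-whitening** by default: annual index series over ≤ 37 values
  are treated as serially independent, which is the common practice for
  this family of analyses. An optional lag-1 pre-whitening mode exists for
  sensitivity checks (it consumes one observation).
* **No multiple-testing adjustment across pixels**: maps show per-pixel
  significance at α (default 0.10), and the changed-area proportion is
  exactly the fraction of valid pixels rejected at that level. Under a
  spatially independent null this proportion concentrates near α, which
  the validation exploits.

## The agroclimatic variables

All windows are inclusive month-day spans evaluated on the real, leap-aware
calendar. The defaults, all exposed in `IndexConfig()`:

* **GDD** — base 10 °C, April 1 – October 31, the conventional viticultural
  choice. Two accumulation methods exist in the field; both are
  implemented: `"simple"` ($\max(0, \bar T - 10)$, the default) and
  `"corn"` (tmin/tmax clamped to [10, 30] °C before averaging). The default
  is the simpler method; the choice is a configuration, not a constant.
* **FFD** — the freeze-to-freeze season length: day-of-year of the first
  fall freeze (searched July 1 – December 31; 366 if none) minus
  day-of-year of the last spring freeze (searched January 1 – June 30; 0 if
  none), a freeze being tmin ≤ 0 °C. This season-length reading (rather
  than a count of individually frost-free days) is what matches typical
  reported ranges of 145–215 days for the region. A year that freezes
  every day floors at 1 (DOY 182 − DOY 181), the adjacent-day difference
  the convention produces.
* **FCD** — days with tmin strictly below −20 °C, a commonly cited
  cold-damage boundary for *V. vinifera*, in the winter window November 1
  (previous year) – March 31, assigned to the year containing January. The
  record's first year is therefore invalid by construction rather than
  computed from a truncated winter.
* **SPRING_T** (Apr 1 – May 31), **PRECIP_GROWTH** (Apr 1 – Jun 30),
  **PRECIP_ROT** (Aug 1 – Oct 31) — the exact phenological windows for
  these derived variables vary between studies and are not standardised;
  the defaults are disjoint early-growth and veraison-to-harvest phases
  and should be treated as configurable stand-ins, not canonical values.
* **GST**, **GS_PRECIP** — growing-season (Apr 1 – Oct 31) temperature
  mean and precipitation total.

**Missing data.** A pixel-year is invalid exactly when any day required by
the variable's window is missing; partial sums are never formed, because a
window sum over a truncated window would bias the very slopes the pipeline
estimates. Invalidity propagates: a pixel with any invalid year inside an
analysis window is invalid for that window's test.

## Analysis windows

`buildWindows()` defaults to nine spans designed for a 37-year 1983–2019
record: the full period, the first and last 20 years, thirds (12/12/13),
the first and last 30 years, and the last 8 years. Overlapping windows are
intentional — they localise when a trend emerged — but their tests are not
independent, which readers of the 72-row summary table should keep in
mind. Custom spans are validated to contain at least 3 years (the minimum
for a Mann-Kendall test) and to lie inside the data's year range.

## The synthetic generator

`generateDailyClimate()` draws from a deliberately transparent model:

* daily mean temperature = annual mean + a single cosine harmonic peaking
  mid-July + a per-row north–south gradient + a linear trend
  × (year − start year) + AR(1) noise;
* tmax/tmin = mean ± half the diurnal range, the half-range perturbed but
  floored at zero so tmax ≥ tmin is a hard invariant;
* precipitation occurrence is Bernoulli per day with a monthly wet
  probability (optionally 2-state Markov with preserved wet frequency);
  wet-day amounts are gamma-distributed and scaled by a linear factor that
  realises a configured mm/yr trend in the expected annual total, clamped
  nonnegative.

One call to `set.seed` with the config's single seed governs every draw,
so a config is a complete recipe: identical config ⇒ bit-identical grid.

The seasonal harmonic is evaluated on a leap-invariant pseudo day-of-year
(February 29 repeats February 28's climatology, later days shift by one).
This makes every calendar date's climatology identical across years, so a
noise-free run with trend β has month-day window means that step by
exactly β per year — the property the trend-recovery tests assert.
February 29 itself participates in no default window. The trend is applied
to daily values, linear in year, which is precisely the quantity Sen's
slope estimates; recovery is therefore a calibration check of the whole
chain, not a tautology (the estimator never sees the generator's
parameters).

**Default parameters** emulate a Michigan Lower-Peninsula-like climate:
mean annual temperature 8.5 °C, seasonal amplitude 13.5 °C, diurnal range
10 °C, gradient −0.05 °C/row, AR(1) 0.6 with marginal noise SD 3.2 °C,
monthly wet-day probabilities 0.30–0.43, gamma wet-day amounts with shape
0.9 and scale 8.5 mm, over 37 years from 1983 on a 20 × 20 grid. These
were calibrated once, by simulation, so that annual GDD, FFD, GST and
growing-season precipitation fall within the typical regional ranges
(750–2040 degree-days, 145–215 days, 11–19 °C, 245–1090 mm) for at least
95% of pixel-years; the calibration is itself a test.

**What the generator does not emulate:** lake-effect snow and moderation,
topographic and coastal structure beyond a linear gradient, spatially
correlated weather (pixels' noise streams are independent, which makes
changed-area proportions *less* variable than on real grids, where
spatial correlation inflates their variance), precipitation persistence
beyond one day, and any nonlinearity in the trend. Passing the validation
therefore demonstrates the correctness and calibration of the machinery —
not that real-data maps would be equally clean.

## Numerical and design notes

* S is accumulated column-wise in O(n²) time but O(n) memory; values must
  be finite, and series shorter than 3 are rejected for testing (2 for S
  and the slope alone).
* The Sen confidence band uses the classical rank construction
  $(N \mp z\sqrt{\operatorname{var}(S)})/2$ on the sorted pairwise slopes,
  with indices clamped to the achievable range.
* The exact-mode null distribution is computed by convolving uniform
  kernels (the inversion-count recursion); at $n \le 10$ the counts are
  exact in double precision.
* Masked slope rasters encode "no significant change" as `NA`, never 0 —
  a zero would be indistinguishable from a genuine zero slope.
  `slopeLayer(x, masked = FALSE)` returns unmasked slopes so users can
  re-threshold with the p-value layer.
* The changed-area denominator is the count of *valid* pixels, and rows
  with no valid pixel (FCD in any window touching the first year) carry
  `NA` proportions rather than failing the whole summary.
* Grids, index cubes and trend rasters serialise to a self-describing
  plain-text container (a YAML header carrying dimensions, units, start
  date and grid spacing above a long CSV table). This keeps every artifact
  diffable and portable; the import adapter reads the same layout with
  arbitrary column names and declared units (°F and inches are converted
  on ingest) and reports all defects — missing variables, unknown units,
  calendar gaps — in one message.
* Daily input is assumed throughout: FFD, FCD and GDD are defined on daily
  extremes and cannot be derived from monthly summaries.

## Problem sizes used in validation

The shipped validation uses: 1000 random tied series (n ≤ 15) for oracle
equivalence against brute-force enumeration; 10,000 iid normal series of
n = 37 for the empirical type-I error at α = 0.10 (expected 10% ± 1 point);
a 20 × 20 × 37-year grid with an injected 0.04 °C/yr warming for
parameter recovery (median pixel Sen's slope within ±0.01 of truth,
changed area > 0.5) plus a matching null run (changed area within binomial
tolerance of α); and one 37-year default-configuration run for the
range calibration. These sizes give stable Monte-Carlo checks at desk
scale; nothing in the method depends on them.

## Known limitations

* The normal approximation for $S$ is the standard choice at n ≥ 8–10 but
  is an approximation; the exact mode covers only short tie-free series.
* No spatial false-discovery control is offered; changed-area proportions
  at small effect sizes should be read against the α baseline, not zero.
* Trend tests assume serially independent annual values; strongly
  autocorrelated series inflate the type-I error, and the optional
  pre-whitening mode is a diagnostic rather than a complete remedy.
* The import adapter expects gap-free daily calendars; records with gaps
  must be masked (NA values are fine, missing dates are not).
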