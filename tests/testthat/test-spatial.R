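# analysis windows, pixel-wise trends, changed-area summaries

trendedCube <- function(nYears = 10, nR = 3, nC = 3, slope = 0.5,
                        noise = 0, seed = 1, startYear = 1983) {
  set.seed(seed)
  yrs <- startYear + seq_len(nYears) - 1L
  arr <- array(0, c(nYears, nR, nC))
  for (r in seq_len(nR)) for (cc in seq_len(nC)) {
    arr[, r, cc] <- slope * seq_len(nYears) + rnorm(nYears, sd = noise)
  }
  IndexCube("GST", yrs, arr, units = "degC")
}

test_that("the default window set is the nine standard spans", {
  w <- buildWindows()
  expect_equal(nrow(w), 9)
  expect_equal(w$n_years[w$label == "1983-2019"], 37)
  expect_equal(w$n_years[w$label == "1983-2002"], 20)
  expect_equal(w$n_years[w$label == "2000-2019"], 20)
  expect_equal(w$n_years[w$label == "1983-1994"], 12)
  expect_equal(w$n_years[w$label == "1995-2006"], 12)
  expect_equal(w$n_years[w$label == "2007-2019"], 13)
  expect_equal(w$n_years[w$label == "1983-2012"], 30)
  expect_equal(w$n_years[w$label == "1990-2019"], 30)
  expect_equal(w$n_years[w$label == "2012-2019"], 8)
  expect_equal(w$end_year - w$start_year + 1L, w$n_years)
})

test_that("degenerate or out-of-range windows are rejected", {
  expect_error(buildWindows(list(c(2000, 2000))), "at least 3")
  expect_error(buildWindows(list(c(2005, 2001))), "start after end")
  expect_error(buildWindows(list(c(1980, 1990)), dataYears = 1983:2019),
               "outside the data years")
  expect_silent(buildWindows(list(c(1983, 2019)), dataYears = 1983:2019))
})

test_that("a noise-free trended cube is significant everywhere with exact slope", {
  cube <- trendedCube(slope = 0.5)
  tr <- pixelwiseTrend(cube, list(label = "1983-1992", start_year = 1983,
                                  end_year = 1992))
  expect_true(all(validityMask(tr)))
  expect_true(all(significanceMask(tr)))
  expect_equal(unname(slopeLayer(tr)), matrix(0.5, 3, 3))
  expect_equal(changedAreaProportion(tr), 1)
  p <- changedAreaProportion(tr, bySign = TRUE)
  expect_equal(unname(p["increasing"]), 1)
  expect_equal(unname(p["decreasing"]), 0)
})

test_that("per-pixel results are identical to calling the test directly", {
  cube <- trendedCube(nYears = 15, slope = 0.1, noise = 1, seed = 9)
  w <- list(label = "1985-1994", start_year = 1985, end_year = 1994)
  tr <- pixelwiseTrend(cube, w, alpha = 0.10)
  sel <- which(indexYears(cube) >= 1985 & indexYears(cube) <= 1994)
  for (r in 1:3) for (cc in 1:3) {
    x <- indexValues(cube)[sel, r, cc]
    res <- mkTest(x, years = indexYears(cube)[sel], alpha = 0.10)
    expect_identical(slopeLayer(tr, masked = FALSE)[r, cc], res@senSlope)
    expect_identical(pValueLayer(tr)[r, cc], res@pValue)
    expect_identical(tauLayer(tr)[r, cc], res@tau)
    expect_identical(significanceMask(tr)[r, cc], res@significant)
  }
})

test_that("window subsetting is inclusive and the full window is the identity", {
  cube <- trendedCube(nYears = 37, slope = 0.02, noise = 0.5, seed = 2)
  w <- list(label = "1983-2019", start_year = 1983, end_year = 2019)
  tr <- pixelwiseTrend(cube, w)
  direct <- mkTest(indexValues(cube)[, 1, 1], years = indexYears(cube))
  expect_identical(slopeLayer(tr, masked = FALSE)[1, 1], direct@senSlope)
  expect_error(pixelwiseTrend(cube, list(label = "x", start_year = 1980,
                                         end_year = 2019)), "cover")
})

test_that("an invalid pixel-year knocks out only that pixel", {
  cube <- trendedCube(slope = 0.5)
  v <- indexValues(cube)
  v[4, 2, 2] <- NA
  cube2 <- IndexCube("GST", indexYears(cube), v, units = "degC")
  tr <- pixelwiseTrend(cube2, list(label = "1983-1992", start_year = 1983,
                                   end_year = 1992))
  expect_false(validityMask(tr)[2, 2])
  expect_false(significanceMask(tr)[2, 2])
  expect_true(is.na(slopeLayer(tr)[2, 2]))
  expect_equal(sum(validityMask(tr)), 8)
  expect_true(all(significanceMask(tr)[-5]))  # [2,2] is element 5
  # masked slope layer uses NA, never zero, for masked pixels
  expect_false(any(slopeLayer(tr) == 0, na.rm = TRUE))
})

test_that("changed-area proportion uses the valid-pixel denominator", {
  cube <- trendedCube(slope = 0.5)
  v <- indexValues(cube)
  v[1, 1, ] <- NA  # 3 invalid pixels
  cube2 <- IndexCube("GST", indexYears(cube), v, units = "degC")
  tr <- pixelwiseTrend(cube2, list(label = "1983-1992", start_year = 1983,
                                   end_year = 1992))
  expect_equal(changedAreaProportion(tr), 1)  # 6 of 6 valid
  # all-invalid raster is an error
  v[] <- NA
  cube3 <- IndexCube("GST", indexYears(cube), v, units = "degC")
  tr3 <- pixelwiseTrend(cube3, list(label = "1983-1992", start_year = 1983,
                                    end_year = 1992))
  expect_error(changedAreaProportion(tr3), "no valid pixels")
})

test_that("proportions are pixel-order invariant and sign splits sum to the total", {
  set.seed(21)
  nY <- 20; nR <- 4; nC <- 5
  arr <- array(rnorm(nY * nR * nC), c(nY, nR, nC))
  arr[, 1:2, ] <- arr[, 1:2, ] + 0.3 * seq_len(nY)  # half trended
  cube <- IndexCube("GDD", 1991:2010, arr, units = "degree-days")
  w <- list(label = "1991-2010", start_year = 1991, end_year = 2010)
  tr <- pixelwiseTrend(cube, w)
  p <- changedAreaProportion(tr, bySign = TRUE)
  expect_equal(unname(p["increasing"] + p["decreasing"]),
               unname(p["total"]))
  # permute pixels: proportion unchanged
  perm <- sample(nR)
  cubeP <- IndexCube("GDD", 1991:2010, arr[, perm, , drop = FALSE],
                     units = "degree-days")
  trP <- pixelwiseTrend(cubeP, w)
  expect_equal(changedAreaProportion(trP), changedAreaProportion(tr))
})

test_that("a half-trended grid yields roughly half changed area plus alpha", {
  set.seed(88)
  nY <- 37; nR <- 10; nC <- 10
  arr <- array(rnorm(nY * nR * nC), c(nY, nR, nC))
  arr[, 1:5, ] <- arr[, 1:5, ] + 0.2 * seq_len(nY)  # power ~ 1 trend
  cube <- IndexCube("GST", 1983:2019, arr, units = "degC")
  tr <- pixelwiseTrend(cube, list(label = "1983-2019", start_year = 1983,
                                  end_year = 2019))
  p <- changedAreaProportion(tr)
  # expectation 0.5 * 1 + 0.5 * 0.10 = 0.55; binomial 3 SE ~ 0.15
  expect_lt(abs(p - 0.55), 0.15)
})

test_that("the summary table enumerates variable x window with coherent counts", {
  g <- generateDailyClimate(GeneratorConfig(nYears = 12, startYear = 1995,
                                            nRows = 3, nCols = 3, seed = 6))
  cubes <- computeAnnualIndices(g)
  w <- buildWindows(list(c(1995, 2006), c(1996, 2003), c(2000, 2006)))
  s <- summarizeTrends(cubes, w)
  expect_equal(nrow(s), 8 * 3)
  expect_setequal(unique(s$variable), names(cubes))
  expect_true(all(s$n_significant <= s$n_valid))
  ok <- !is.na(s$prop_changed)
  expect_equal(s$prop_changed[ok],
               (s$prop_increasing + s$prop_decreasing)[ok])
  # FCD has no valid pixels in windows starting at the first year
  expect_true(is.na(s$prop_changed[s$variable == "FCD" &
                                     s$window == "1995-2006"]))
  expect_equal(s$n_valid[s$variable == "FCD" & s$window == "1996-2003"], 9)
})
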