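# agroclimatic index engine

test_that("daily mean temperature is the tmin/tmax midpoint", {
  expect_equal(dailyMeanTemperature(10, 20), 15)
  expect_equal(dailyMeanTemperature(-5, -5), -5)
  expect_equal(dailyMeanTemperature(0, 7), 3.5)
  expect_error(dailyMeanTemperature(10, 5), "tmax")
})

test_that("GDD on constant-temperature years matches calendar arithmetic", {
  # Tmean 15, base 10, April 1 - October 31 spans 214 days: 5 * 214 = 1070
  g <- constantGrid(2001, 1, 10, 20, 0)
  expect_equal(growingDegreeDays(g, 2001)[1, 1], 1070)
  # the window has the same length in a leap year (it excludes February)
  gl <- constantGrid(2000, 1, 10, 20, 0)
  expect_equal(growingDegreeDays(gl, 2000)[1, 1], 1070)
  # below-base days contribute nothing
  g8 <- constantGrid(2001, 1, 3, 13, 0)
  expect_equal(growingDegreeDays(g8, 2001)[1, 1], 0)
})

test_that("corn method clamps tmin/tmax into [base, 30] before averaging", {
  d <- yearDates(2001)
  set.seed(33)
  tmin <- runif(length(d), -15, 18)
  tmax <- tmin + runif(length(d), 0, 20)
  g <- onePixelGrid(d, tmin, tmax, rep(0, length(d)))
  for (m in c("simple", "corn")) {
    cfg <- IndexConfig(gddMethod = m)
    expect_equal(growingDegreeDays(g, 2001, cfg)[1, 1],
                 bruteForceGDD(d, tmin, tmax, 2001, method = m))
  }
  # corn GDD is nonnegative by construction
  expect_gte(growingDegreeDays(g, 2001, IndexConfig(gddMethod = "corn"))[1, 1], 0)
})

test_that("frost-free season length follows the freeze-to-freeze convention", {
  d <- yearDates(2001)
  doy <- seq_along(d)
  # freezes exactly on DOY 120 (spring) and DOY 290 (fall): FFD = 170
  tmin <- rep(5, length(d))
  tmin[doy <= 120] <- -2
  tmin[doy >= 290] <- -2
  g <- onePixelGrid(d, tmin, tmin + 10, rep(0, length(d)))
  expect_equal(frostFreeDays(g, 2001)[1, 1], 170)
  # no freeze at all: endpoints default to 0 and 366
  gwarm <- constantGrid(2001, 1, 2, 12, 0)
  expect_equal(frostFreeDays(gwarm, 2001)[1, 1], 366)
  # every day freezing: last spring freeze Jun 30 (181), first fall freeze
  # Jul 1 (182), season floors at the adjacent-day difference
  gcold <- constantGrid(2001, 1, -5, 1, 0)
  expect_equal(frostFreeDays(gcold, 2001)[1, 1], 1)
  # threshold boundary: a day at exactly 0 is a freeze (<=)
  tmin2 <- rep(5, length(d)); tmin2[100] <- 0
  g2 <- onePixelGrid(d, tmin2, tmin2 + 10, rep(0, length(d)))
  expect_equal(frostFreeDays(g2, 2001)[1, 1], 366 - 100)
})

test_that("cold-day frequency counts strictly-below-threshold winter days", {
  d <- yearDates(2000, 2)
  tmin <- rep(-5, length(d))
  # five damaging days in Dec 2000 belong to winter-2001
  cold <- d >= as.Date("2000-12-10") & d <= as.Date("2000-12-14")
  tmin[cold] <- -25
  g <- onePixelGrid(d, tmin, tmin + 8, rep(0, length(d)))
  expect_equal(coldDayFrequency(g, 2001)[1, 1], 5)
  # a day at exactly the threshold does not count (strict <)
  tmin3 <- rep(-5, length(d)); tmin3[cold] <- -20
  g3 <- onePixelGrid(d, tmin3, tmin3 + 8, rep(0, length(d)))
  expect_equal(coldDayFrequency(g3, 2001)[1, 1], 0)
  # first year's preceding winter is unavailable
  expect_true(is.na(coldDayFrequency(g, 2000)[1, 1]))
})

test_that("windowed precipitation totals match calendar arithmetic", {
  g <- constantGrid(2001, 1, 5, 15, 1)
  expect_equal(windowedPrecipTotal(g, 2001, c("04-01", "10-31"))[1, 1], 214)
  g0 <- constantGrid(2001, 1, 5, 15, 0)
  expect_equal(windowedPrecipTotal(g0, 2001, c("04-01", "10-31"))[1, 1], 0)
})

test_that("windowed temperature means hit constant and alternating cases", {
  g <- constantGrid(2001, 1, 9, 19, 0)  # Tmean 14 everywhere
  expect_equal(windowedTempMean(g, 2001, c("04-01", "10-31"))[1, 1], 14)
  d <- yearDates(2001)
  tm <- ifelse(seq_along(d) %% 2 == 0, 20, 10)
  g2 <- onePixelGrid(d, tm - 5, tm + 5, rep(0, length(d)))
  # April 1 - October 31 covers 214 days, an even count: mean is 15
  expect_equal(windowedTempMean(g2, 2001, c("04-01", "10-31"))[1, 1], 15)
})

test_that("every index equals its brute-force day loop on random years", {
  set.seed(404)
  for (i in 1:5) {
    d <- yearDates(2000, 2)
    n <- length(d)
    tmin <- rnorm(n, 5, 12)
    tmax <- tmin + runif(n, 0, 12)
    precip <- ifelse(runif(n) < 0.4, rgamma(n, 0.8, scale = 9), 0)
    g <- onePixelGrid(d, tmin, tmax, precip)
    cfg <- IndexConfig(coldThreshold = -8)  # ensure some cold days occur
    expect_equal(growingDegreeDays(g, 2001)[1, 1],
                 bruteForceGDD(d, tmin, tmax, 2001))
    expect_equal(frostFreeDays(g, 2001)[1, 1],
                 bruteForceFFD(d, tmin, 2001))
    expect_equal(coldDayFrequency(g, 2001, cfg)[1, 1],
                 bruteForceFCD(d, tmin, 2001, threshold = -8))
    expect_equal(windowedPrecipTotal(g, 2001, c("08-01", "10-31"))[1, 1],
                 bruteForcePrecipSum(d, precip, 2001, "08-01", "10-31"))
  }
})

test_that("index responses to thresholds are monotone", {
  set.seed(55)
  d <- yearDates(2001)
  n <- length(d)
  tmin <- rnorm(n, 4, 10)
  tmax <- tmin + runif(n, 0, 12)
  g <- onePixelGrid(d, tmin, tmax, rep(0, n))
  # raising the GDD base never increases GDD
  gdd <- vapply(c(5, 8, 10, 12), function(b) {
    growingDegreeDays(g, 2001, IndexConfig(gddBase = b))[1, 1]
  }, numeric(1))
  expect_true(all(diff(gdd) <= 0))
  # raising the freeze threshold never increases FFD
  ffd <- vapply(c(-4, -2, 0, 2), function(thr) {
    frostFreeDays(g, 2001, IndexConfig(freezeThreshold = thr))[1, 1]
  }, numeric(1))
  expect_true(all(diff(ffd) <= 0))
  # lowering the cold threshold never increases FCD
  fcd <- vapply(c(-2, -6, -10, -14), function(thr) {
    coldDayFrequency(constantGrid(2000, 2, -8, 0, 0), 2001,
                     IndexConfig(coldThreshold = thr))[1, 1]
  }, numeric(1))
  expect_true(all(diff(fcd) <= 0))
})

test_that("abutting precipitation windows are additive", {
  set.seed(66)
  d <- yearDates(2001)
  precip <- rgamma(length(d), 0.7, scale = 8)
  g <- onePixelGrid(d, rep(0, length(d)), rep(10, length(d)), precip)
  a <- windowedPrecipTotal(g, 2001, c("04-01", "06-30"))[1, 1]
  b <- windowedPrecipTotal(g, 2001, c("07-01", "10-31"))[1, 1]
  u <- windowedPrecipTotal(g, 2001, c("04-01", "10-31"))[1, 1]
  expect_equal(a + b, u)
})

test_that("computeAnnualIndices assembles eight aligned cubes with correct masks", {
  g <- generateDailyClimate(GeneratorConfig(nYears = 3, nRows = 2, nCols = 2,
                                            seed = 14))
  cubes <- computeAnnualIndices(g)
  expect_named(cubes, c("GDD", "FCD", "FFD", "SPRING_T", "PRECIP_GROWTH",
                        "PRECIP_ROT", "GST", "GS_PRECIP"))
  for (v in names(cubes)) {
    expect_s4_class(cubes[[v]], "IndexCube")
    expect_equal(indexYears(cubes[[v]]), 1983:1985)
    expect_equal(dim(indexValues(cubes[[v]])), c(3, 2, 2))
  }
  # FCD's first year lacks its preceding November-December
  expect_true(all(is.na(indexValues(cubes$FCD)[1, , ])))
  expect_true(all(!is.na(indexValues(cubes$FCD)[2:3, , ])))
  # nonnegativity of counts and sums where valid
  for (v in c("GDD", "FCD", "FFD", "PRECIP_GROWTH", "PRECIP_ROT",
              "GS_PRECIP")) {
    expect_true(all(indexValues(cubes[[v]]) >= 0, na.rm = TRUE))
  }
  expect_true(all(indexValues(cubes$FFD) <= 366, na.rm = TRUE))
})

test_that("a single missing day invalidates exactly the windows that need it", {
  g <- generateDailyClimate(GeneratorConfig(nYears = 3, nRows = 2, nCols = 2,
                                            seed = 15))
  i <- which(climDates(g) == as.Date("1984-07-10"))
  g@tmin[i, 1, 1] <- NA
  g@tmax[i, 1, 1] <- NA
  g@precip[i, 1, 1] <- NA
  cubes <- computeAnnualIndices(g)
  y <- 2  # 1984
  for (v in c("GDD", "GST", "GS_PRECIP", "FFD")) {
    expect_true(is.na(indexValues(cubes[[v]])[y, 1, 1]), label = v)
  }
  # July is outside the spring and rot windows: those stay valid
  for (v in c("SPRING_T", "PRECIP_ROT", "PRECIP_GROWTH")) {
    expect_false(is.na(indexValues(cubes[[v]])[y, 1, 1]), label = v)
  }
  # neighbouring pixels are untouched
  expect_false(is.na(indexValues(cubes$GDD)[y, 2, 2]))
})

test_that("an incomplete grid is rejected and config windows are validated", {
  d <- seq(as.Date("2001-03-01"), as.Date("2001-10-01"), by = "day")
  g <- onePixelGrid(d, rep(1, length(d)), rep(9, length(d)),
                    rep(0, length(d)))
  expect_error(computeAnnualIndices(g), "complete calendar year")
  expect_error(IndexConfig(seasonStart = "10-01", seasonEnd = "04-30"),
               "season")
  expect_error(IndexConfig(coldThreshold = 5), "coldThreshold")
})
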