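# Independent brute-force oracles, written as plain day/pair loops with no
# shared code with the package internals. They define the expected values
# for the statistic and index engines.

# Mann-Kendall S: explicit double loop over ordered pairs with the three
# sign cases spelled out
bruteForceS <- function(x) {
  n <- length(x)
  s <- 0L
  for (k in seq_len(n - 1L)) {
    for (j in (k + 1L):n) {
      d <- x[j] - x[k]
      if (d > 0) s <- s + 1L else if (d < 0) s <- s - 1L
    }
  }
  s
}

# Sen's slope: materialise the full pairwise slope list, then take its median
bruteForceSen <- function(x, years = seq_along(x)) {
  slopes <- c()
  n <- length(x)
  for (k in seq_len(n - 1L)) {
    for (j in (k + 1L):n) {
      slopes <- c(slopes, (x[j] - x[k]) / (years[j] - years[k]))
    }
  }
  median(slopes)
}

# day-loop growing degree days for a single pixel-year
bruteForceGDD <- function(dates, tmin, tmax, year, base = 10,
                          method = "simple",
                          startMD = "04-01", endMD = "10-31") {
  s <- as.Date(sprintf("%d-%s", year, startMD))
  e <- as.Date(sprintf("%d-%s", year, endMD))
  total <- 0
  for (i in seq_along(dates)) {
    if (dates[i] >= s && dates[i] <= e) {
      if (is.na(tmin[i]) || is.na(tmax[i])) return(NA_real_)
      if (method == "corn") {
        lo <- min(max(tmin[i], base), 30)
        hi <- min(max(tmax[i], base), 30)
        total <- total + (lo + hi) / 2 - base
      } else {
        dd <- (tmin[i] + tmax[i]) / 2 - base
        if (dd > 0) total <- total + dd
      }
    }
  }
  total
}

# day-loop frost-free season length for a single pixel-year
bruteForceFFD <- function(dates, tmin, year, threshold = 0) {
  lastSpring <- 0
  firstFall <- 366
  for (i in seq_along(dates)) {
    yr <- as.integer(format(dates[i], "%Y"))
    if (yr != year) next
    if (is.na(tmin[i])) return(NA_real_)
    doy <- as.integer(strftime(dates[i], "%j"))
    inSpring <- dates[i] <= as.Date(sprintf("%d-06-30", year))
    if (tmin[i] <= threshold) {
      if (inSpring) {
        if (doy > lastSpring) lastSpring <- doy
      } else {
        if (doy < firstFall) firstFall <- doy
      }
    }
  }
  max(0, firstFall - lastSpring)
}

# day-loop cold-day count for the winter assigned to 'year'
bruteForceFCD <- function(dates, tmin, year, threshold = -20,
                          startMD = "11-01", endMD = "03-31") {
  s <- as.Date(sprintf("%d-%s", year - 1L, startMD))
  e <- as.Date(sprintf("%d-%s", year, endMD))
  if (s < dates[1] || e > dates[length(dates)]) return(NA_real_)
  count <- 0
  for (i in seq_along(dates)) {
    if (dates[i] >= s && dates[i] <= e) {
      if (is.na(tmin[i])) return(NA_real_)
      if (tmin[i] < threshold) count <- count + 1
    }
  }
  count
}

# day-loop windowed precipitation sum
bruteForcePrecipSum <- function(dates, precip, year, startMD, endMD) {
  s <- as.Date(sprintf("%d-%s", year, startMD))
  e <- as.Date(sprintf("%d-%s", year, endMD))
  total <- 0
  for (i in seq_along(dates)) {
    if (dates[i] >= s && dates[i] <= e) {
      if (is.na(precip[i])) return(NA_real_)
      total <- total + precip[i]
    }
  }
  total
}

# build a 1 x 1 ClimateGrid from per-day vectors (test fixture helper)
onePixelGrid <- function(dates, tmin, tmax, precip) {
  nT <- length(dates)
  ClimateGrid(dates = dates,
              tmin = array(tmin, c(nT, 1, 1)),
              tmax = array(tmax, c(nT, 1, 1)),
              precip = array(precip, c(nT, 1, 1)))
}

# full-year date sequence
yearDates <- function(year, nYears = 1) {
  seq(as.Date(sprintf("%d-01-01", year)),
      as.Date(sprintf("%d-12-31", year + nYears - 1)), by = "day")
}

# constant-climate single pixel grid over full years
constantGrid <- function(year, nYears, tminVal, tmaxVal, precipVal) {
  d <- yearDates(year, nYears)
  onePixelGrid(d, rep(tminVal, length(d)), rep(tmaxVal, length(d)),
               rep(precipVal, length(d)))
}
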