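test_that("single triangulation matches its closed-form regimes", {
  expect_equal(singleTriangulation(10, 20), 9.5)        # fully above threshold
  expect_equal(singleTriangulation(2, 4), 0)            # fully below
  expect_equal(singleTriangulation(0, 11), 1.375)       # threshold-crossing
  expect_error(singleTriangulation(10, 5), "tmax < tmin")

  # continuity at tmin = T_L: both branches give (tmax - T_L)/2
  lo <- singleTriangulation(5.5, 20)
  hi <- singleTriangulation(5.5 + 1e-12, 20)
  expect_equal(lo, (20 - 5.5) / 2)
  expect_equal(hi, lo, tolerance = 1e-9)

  # upper threshold subtracts the apex triangle
  withUpper <- singleTriangulation(10, 44, tUpper = 38)
  apex <- (44 - 38)^2 / (2 * (44 - 10))
  expect_equal(withUpper, singleTriangulation(10, 44) - apex)
})

test_that("single triangulation agrees with the triangle-geometry oracle", {
  set.seed(8)
  tmin <- runif(500, -20, 25)
  tmax <- tmin + runif(500, 0, 25)
  thr <- runif(500, 0, 15)
  err <- vapply(seq_len(500), function(i)
    abs(singleTriangulation(tmin[i], tmax[i], thr[i]) -
          triangleAreaOracle(tmin[i], tmax[i], thr[i])), 0)
  expect_lt(max(err), 1e-9)
})

test_that("logger calibration applies per-series median corrections", {
  days <- as.Date("2018-06-01") + 0:29
  station <- data.frame(date = days, tmin = 5 + sin(1:30), tmax = 15 + sin(1:30))
  logger <- station
  logger$tmax <- station$tmax + 1.5
  logger$tmin <- station$tmin + 0.8
  cal <- calibrateTemperature(logger, station)
  expect_equal(cal$medianHigh, 1.5)
  expect_equal(cal$medianLow, 0.8)
  expect_equal(cal$corrected$tmax, logger$tmax)
  expect_equal(cal$corrected$tmin, logger$tmin)

  # identical series: zero correction, series unchanged
  cal0 <- calibrateTemperature(station, station)
  expect_equal(cal0$medianHigh, 0)
  expect_equal(cal0$corrected$tmax, station$tmax)
  expect_gt(cal0$testHigh$p, 0.9)

  # median of diffs [1.0, 2.0, -0.5] is 1.0
  s3 <- data.frame(date = days[1:3], tmin = c(0, 0, 0), tmax = c(10, 10, 10))
  l3 <- s3; l3$tmax <- s3$tmax + c(1, 2, -0.5); l3$tmin <- s3$tmin + c(1, 2, -0.5)
  expect_equal(calibrateTemperature(l3, s3)$medianHigh, 1)

  off <- station; off$date <- off$date + 100
  expect_error(calibrateTemperature(off, station), "overlap")
})

test_that("degree-day accumulation is cumulative, non-negative and interpolates gaps", {
  days <- as.Date("2018-01-01") + 0:9
  t1 <- data.frame(location = "L", date = days, tmin = 10, tmax = 20)
  dd <- accumulateDegreeDays(t1)
  expect_equal(dd$cumdd[10], 95)                 # 10 x 9.5
  expect_equal(dd$dd, rep(9.5, 10))

  cold <- data.frame(location = "L", date = days, tmin = -10, tmax = 0)
  expect_true(all(accumulateDegreeDays(cold)$cumdd == 0))

  set.seed(2)
  rnd <- data.frame(location = "L", date = days,
                    tmin = runif(10, -5, 10), tmax = runif(10, 10, 25))
  ddr <- accumulateDegreeDays(rnd)
  expect_equal(ddr$cumdd, cumsum(singleTriangulation(rnd$tmin, rnd$tmax)))
  expect_true(all(diff(ddr$cumdd) >= 0))

  gap <- t1[-5, ]
  ddg <- accumulateDegreeDays(gap)
  expect_equal(nrow(ddg), 10)
  expect_equal(attr(ddg, "interpolated"), 1L)
  expect_equal(ddg$dd[5], 9.5)                   # linear fill of a flat series
})

test_that("collection-day degree-days join inclusively by location and date", {
  days <- as.Date("2018-01-01") + 0:9
  ddt <- accumulateDegreeDays(data.frame(location = "L", date = days,
                                         tmin = 10, tmax = 20))
  s <- data.frame(id = c("a", "b", "c"), location = "L",
                  date = as.Date(c("2018-01-03", "2018-01-03", "2018-01-10")))
  out <- ddAtCollection(ddt, s)
  expect_equal(out$dd, c(3, 3, 10) * 9.5)        # through day d inclusive
  outEx <- ddAtCollection(ddt, s, inclusive = FALSE)
  expect_equal(outEx$dd, c(2, 2, 9) * 9.5)
  s$date[1] <- as.Date("2017-12-31")
  expect_error(ddAtCollection(ddt, s), "outside")
})

test_that("zero-offset synthetic calibration is statistically null", {
  ps <- vapply(1:10, function(s) {
    t <- simulateTemperature("a", 2018, loggerOffsetC = 0, seed = s,
                             loggerNoiseSd = 0.2)
    cal <- calibrateTemperature(t[t$source == "logger", ],
                                t[t$source == "station", ])
    cal$testHigh$p
  }, 0)
  # p-values should look uniform, not pile up near 0
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps < 0.05), 0.3)
})
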