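test_that("standard-atmosphere pressure matches direct evaluation and is monotone", {
  expect_equal(calc_air_pressure(0), 101325)
  expect_equal(calc_air_pressure(1500), 84555.99, tolerance = 1e-6)
  expect_lt(calc_air_pressure(2000), calc_air_pressure(1000))
  expect_error(calc_air_pressure(NA), "finite")
  expect_error(calc_air_pressure(Inf), "finite")
})

test_that("oxygen saturation matches an independently coded solubility oracle", {
  # separate implementation: Horner evaluation of the Garcia-Gordon
  # Benson-Krause fit plus Magnus vapor correction
  oracle <- function(T, P) {
    Ts <- log((298.15 - T) / (273.15 + T))
    A <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
    lnC <- A[6]
    for (k in 5:1) lnC <- lnC * Ts + A[k]
    pv <- 610.94 * exp(17.625 * T / (243.04 + T))
    exp(lnC) * 1.42905 * (P - pv) / (101325 - pv)
  }
  grid <- expand.grid(T = seq(1, 35, length.out = 10),
                      P = seq(80000, 104000, length.out = 10))
  got <- as.numeric(calc_DO_sat(grid$T, grid$P))
  expect_lt(max(abs(got - oracle(grid$T, grid$P))), 1e-6)
  expect_equal(as.numeric(calc_DO_sat(20, 101325)), 9.09, tolerance = 0.02 / 9.09)
})

test_that("oxygen saturation is monotone and near-proportional to pressure", {
  expect_lt(as.numeric(calc_DO_sat(30, 101325)),
            as.numeric(calc_DO_sat(10, 101325)))
  r <- as.numeric(calc_DO_sat(20, 2 * 101325)) /
    as.numeric(calc_DO_sat(20, 101325))
  expect_equal(r, 2, tolerance = 0.03)  # vapor-pressure correction only
  expect_warning(calc_DO_sat(50, 101325), "fit range")
  expect_true(attr(suppressWarnings(calc_DO_sat(50, 101325)),
                   "extrapolated"))
})

test_that("solar-time conversion shifts 4 min per degree and bounds the equation of time", {
  t0 <- as.POSIXct("2015-06-21 12:00:00", tz = "UTC")
  expect_equal(convert_UTC_to_solartime(t0, 0, "mean"), t0)
  expect_equal(as.numeric(convert_UTC_to_solartime(t0, -90, "mean") - t0,
                          units = "hours"), -6)
  days <- as.POSIXct("2015-01-01 12:00:00", tz = "UTC") + (0:364) * 86400
  diff_min <- as.numeric(convert_UTC_to_solartime(days, 0, "apparent") -
                           convert_UTC_to_solartime(days, 0, "mean"),
                         units = "mins")
  expect_lt(max(abs(diff_min)), 17)
  expect_gt(max(abs(diff_min)), 13)  # the series is not degenerate
})

test_that("modeled light is zero at night, peaks at noon, and tracks season", {
  midnight <- as.POSIXct("2015-06-21 00:00:00", tz = "UTC")
  expect_equal(calc_light(midnight, 40), 0)
  day <- as.POSIXct("2015-06-21 00:00:00", tz = "UTC") + seq(0, 86100, 300)
  ppfd <- calc_light(day, 40)
  expect_true(all(ppfd >= 0))
  noon <- as.POSIXct("2015-06-21 12:00:00", tz = "UTC")
  expect_equal(max(ppfd), calc_light(noon, 40), tolerance = 1e-6)
  daylight_hours <- function(date) {
    tt <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + seq(0, 86100, 300)
    sum(calc_light(tt, 45) > 0) * 300 / 3600
  }
  expect_gt(daylight_hours("2015-06-21"), daylight_hours("2015-12-21"))
})

test_that("shortwave-to-PAR conversion is the fixed linear multiplier", {
  expect_equal(convert_SW_to_PAR(0), 0)
  expect_equal(convert_SW_to_PAR(500), 1057)
  a <- runif(5, 0, 800); b <- runif(5, 0, 800)
  expect_equal(convert_SW_to_PAR(a + b),
               convert_SW_to_PAR(a) + convert_SW_to_PAR(b))
  expect_equal(convert_SW_to_PAR(-3), 0)  # clipped sensor noise
})

test_that("light merging reproduces observed values and interpolates cloud dips", {
  fine_t <- as.POSIXct("2015-06-21 10:00:00", tz = "UTC") + seq(0, 7200, 900)
  coarse_t <- as.POSIXct("2015-06-21 10:00:00", tz = "UTC") + c(0, 3600, 7200)
  mod_val <- c(1000, 1100, 1200, 1300, 1400, 1500, 1600, 1700, 1800)
  mod <- stream_ts("s", "par_calcLat", fine_t, mod_val)
  # unit ratio: observed equals modeled at the coarse points
  obs1 <- stream_ts("s", "par_calcSw", coarse_t, c(1000, 1400, 1800))
  expect_equal(calc_light_merged(mod, obs1)$data$value, mod_val)
  # constant half ratio
  obs2 <- stream_ts("s", "par_calcSw", coarse_t, c(500, 700, 900))
  expect_equal(calc_light_merged(mod, obs2)$data$value, 0.5 * mod_val)
  # cloud dip at the middle coarse point: hand-computed V-shaped ratios
  obs3 <- stream_ts("s", "par_calcSw", coarse_t, c(1000, 700, 1800))
  ratio <- approx(c(0, 3600, 7200), c(1, 0.5, 1),
                  xout = seq(0, 7200, 900))$y
  expect_equal(calc_light_merged(mod, obs3)$data$value, mod_val * ratio)
})

test_that("merged light is zero wherever modeled light is zero", {
  fine_t <- as.POSIXct("2015-06-21 03:00:00", tz = "UTC") + seq(0, 7200, 900)
  mod <- stream_ts("s", "par_calcLat", fine_t, c(0, 0, 0, 10, 50, 120, 200, 300, 400))
  coarse_t <- fine_t[c(1, 5, 9)]
  obs <- stream_ts("s", "par_calcSw", coarse_t, c(0, 40, 360))
  out <- calc_light_merged(mod, obs)$data$value
  expect_equal(out[1:3], c(0, 0, 0))
  expect_true(all(out >= 0))
})

test_that("hydraulic power laws evaluate exactly and reject nonpositive flow", {
  expect_equal(depth_from_discharge(1, c(c = 0.37, f = 0.41)), 0.37)
  expect_equal(depth_from_discharge(10, c(c = 0.2, f = 0.3)), 0.2 * 10^0.3)
  expect_equal(depth_from_discharge(10, c(c = 0.2, f = 0.3)), 0.3990,
               tolerance = 2e-4)
  expect_equal(depth_from_discharge(7, c(c = 0.5, f = 0)), 0.5)
  expect_true(is.na(depth_from_discharge(0, c(c = 0.2, f = 0.3))))
  expect_true(is.na(velocity_from_discharge(-2, c(k = 0.3, m = 0.2))))
  expect_equal(velocity_from_discharge(4, c(k = 0.3, m = 0.5)), 0.6)
  expect_equal(cfs_to_cms(1), 0.0283168)
})

test_that("percent saturation is the observed/saturation ratio", {
  expect_equal(percent_saturation(10, 10), 100)
  expect_equal(percent_saturation(8, 10), 80)
  expect_equal(percent_saturation(12, 9.09), 132.0, tolerance = 1e-3)
  expect_error(percent_saturation(8, 0), "> 0")
})

test_that("daily aggregation uses 4am-3:59am mean-solar windows without losing observations", {
  # longitude -90: mean solar = UTC - 6 h
  utc <- as.POSIXct("2015-06-10 00:00:00", tz = "UTC") + seq(0, 4 * 86400 - 1800, 1800)
  ts <- stream_ts("s", "wtr_nwis", utc, rep(15, length(utc)))
  agg <- daily_aggregate(ts, "mean", -90)
  expect_true(all(agg$value == 15))
  expect_equal(sum(tapply(rep(1, length(utc)),
                          metab_date(convert_UTC_to_solartime(utc, -90)),
                          sum)),
               length(utc))
  rng <- daily_aggregate(ts, "range", -90)
  expect_true(all(rng$value == 0))
  # a value at mean-solar 03:30 on date d belongs to metabolism date d-1
  one <- stream_ts("s", "wtr_nwis",
                   as.POSIXct("2015-06-10 09:30:00", tz = "UTC"),  # solar 03:30
                   7, resolution = 30)
  expect_equal(daily_aggregate(one, "mean", -90)$date,
               as.Date("2015-06-09"))
})

test_that("daylight-hour counting recovers the positive support of a sinusoid", {
  utc <- as.POSIXct("2015-06-10 06:00:00", tz = "UTC") + seq(0, 86400 - 900, 900)
  solar_hour <- (as.numeric(convert_UTC_to_solartime(utc, -90)) %% 86400) / 3600
  ppfd <- 1500 * pmax(0, sin(pi * (solar_hour - 6) / 12))  # positive 06-18h
  ts <- stream_ts("s", "par_calcLatSw", utc, ppfd)
  agg <- daily_aggregate(ts, "count_positive_hours", -90)
  expect_equal(agg$value[agg$date == as.Date("2015-06-10")], 12,
               tolerance = 0.3 / 12)
})
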