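#' Barometric pressure from site elevation
#'
#' International standard atmosphere: `P = 101325 * (1 - 2.25577e-5 * h)^5.25588`.
#' Used as a simple elevation-only alternative to reanalysis surface pressure.
#'
#' @param altitude Elevation above datum, m. Must be finite and > -500.
#' @return Air pressure, Pa.
#' @export
calc_air_pressure <- function(altitude) {
  if (any(!is.finite(altitude))) stop("altitude must be finite")
  if (any(altitude <= -500)) stop("altitude must be > -500 m")
  101325 * (1 - 2.25577e-5 * altitude)^5.25588
}

# Garcia-Gordon (1992) refit of the Benson-Krause oxygen solubility data;
# returns equilibrium [O2] (mg L-1) for moist air at 1 atm total pressure.
garcia_gordon_1atm <- function(temp_C) {
  Ts <- log((298.15 - temp_C) / (273.15 + temp_C))
  A <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  lnC <- A[1] + A[2] * Ts + A[3] * Ts^2 + A[4] * Ts^3 + A[5] * Ts^4 + A[6] * Ts^5
  exp(lnC) * 1.42905  # mL L-1 -> mg L-1
}

# saturation water vapor pressure, Pa (Magnus-type formula)
water_vapor_pressure <- function(temp_C) {
  610.94 * exp(17.625 * temp_C / (243.04 + temp_C))
}

#' Oxygen saturation concentration
#'
#' Equilibrium dissolved-oxygen concentration for given water temperature and
#' barometric pressure: the Garcia-Gordon (Benson-Krause coefficient set)
#' solubility fit at 1 atm, corrected for barometric pressure by
#' `(P - p_vapor) / (101325 - p_vapor)` with the water vapor pressure from a
#' Magnus-type formula. Strictly decreasing in temperature and increasing in
#' pressure.
#'
#' @param temp_water Water temperature, degrees C. Values outside the
#'   solubility fit range `[-1, 45]` trigger a warning and are flagged in the
#'   `"extrapolated"` attribute.
#' @param pressure_air Barometric pressure, Pa (> 0).
#' @return Saturation concentration, mg O2 L-1, with logical attribute
#'   `"extrapolated"` marking out-of-range temperatures.
#' @export
calc_DO_sat <- function(temp_water, pressure_air) {
  if (any(pressure_air <= 0, na.rm = TRUE)) stop("pressure_air must be > 0")
  extra <- !is.na(temp_water) & (temp_water < -1 | temp_water > 45)
  if (any(extra))
    warning("water temperature outside the solubility fit range [-1, 45] C; extrapolating")
  pv <- water_vapor_pressure(temp_water)
  out <- garcia_gordon_1atm(temp_water) * (pressure_air - pv) / (101325 - pv)
  attr(out, "extrapolated") <- extra
  out
}

# Spencer's Fourier-series equation of time, minutes (accurate to < 1 min)
equation_of_time_min <- function(jday) {
  g <- 2 * pi * (jday - 1) / 365
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

#' Convert UTC clock time to local solar time
#'
#' Mean solar time shifts UTC by 4 minutes per degree longitude (every day
#' exactly 24 h; used to assign observations to metabolism days). Apparent
#' solar time additionally applies the equation of time (Spencer's series) so
#' that noon matches the sun's zenith; used to model light.
#'
#' The returned `POSIXct` keeps the UTC label; its clock reading is the local
#' solar time.
#'
#' @param datetime `POSIXct` instants (UTC).
#' @param longitude Decimal degrees east (negative west).
#' @param mode `"mean"` or `"apparent"`.
#' @return `POSIXct` solar instants.
#' @export
convert_UTC_to_solartime <- function(datetime, longitude,
                                     mode = c("mean", "apparent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(datetime, "POSIXct"))
  out <- datetime + longitude * 240
  if (mode == "apparent") {
    jday <- as.integer(format(out, "%j", tz = "UTC"))
    out <- out + equation_of_time_min(jday) * 60
  }
  attr(out, "tzone") <- "UTC"
  out
}

#' Modeled above-cloud photosynthetic photon flux density
#'
#' Clear-atmosphere PPFD from solar geometry:
#' `PPFD = max_ppfd * max(0, sin(solar elevation))`, with solar declination
#' from Cooper's formula and the hour angle from apparent solar time. Zero
#' when the sun is below the horizon; each day's maximum falls at apparent
#' solar noon.
#'
#' @param solar_time Apparent solar time (`POSIXct`, from
#'   [convert_UTC_to_solartime] with `mode = "apparent"`).
#' @param latitude Decimal degrees north, `|latitude| <= 90`.
#' @param max_ppfd PPFD at unit `sin(elevation)`, umol m-2 s-1.
#' @return PPFD, umol photons m-2 s-1 (nonnegative).
#' @export
calc_light <- function(solar_time, latitude, max_ppfd = 2326) {
  stopifnot(abs(latitude) <= 90)
  jday <- as.integer(format(solar_time, "%j", tz = "UTC"))
  hour <- as.numeric(solar_time) %% 86400 / 3600
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + jday) / 365)
  H <- (hour - 12) * 15 * pi / 180
  phi <- latitude * pi / 180
  sinel <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  max_ppfd * pmax(0, sinel)
}

#' Convert shortwave radiation to PPFD
#'
#' Fixed multiplier conversion (default 2.114 umol J-1, i.e. roughly 45% of
#' shortwave energy in the photosynthetically active band). Small negative
#' inputs (sensor noise) are clipped to zero.
#'
#' @param sw Downward shortwave radiation flux, W m-2.
#' @param coef Multiplier, umol J-1.
#' @return PPFD, umol m-2 s-1.
#' @export
convert_SW_to_PAR <- function(sw, coef = 2.114) {
  coef * pmax(0, sw)
}

#' Merge modeled and observation-based light
#'
#' Downscales coarse (e.g. hourly reanalysis) observation-based PPFD onto the
#' fine timestamps of a modeled clear-sky PPFD series by multiplying the
#' modeled series by the linearly interpolated ratio of observed to modeled
#' light, anchored at the coarse timestamps. Cloud-driven dips in the coarse
#' series become smooth scalings of the fine series. Where modeled light is
#' zero (night) the ratio is undefined; it is carried across by interpolation
#' and the output is forced to zero there.
#'
#' @param modeled [stream_ts] of modeled PPFD on fine timestamps
#'   (`par_calcLat`-style).
#' @param observed [stream_ts] of observation-derived PPFD on coarse
#'   timestamps (`par_calcSw`-style), spanning within the modeled series.
#' @return [stream_ts] of merged PPFD (`par_calcLatSw`) on the fine
#'   timestamps.
#' @export
calc_light_merged <- function(modeled, observed) {
  stopifnot(inherits(modeled, "stream_ts"), inherits(observed, "stream_ts"))
  tf <- as.numeric(modeled$data$DateTime)
  tc <- as.numeric(observed$data$DateTime)
  mod_c <- approx(tf, modeled$data$value, xout = tc, rule = 2)$y
  ratio <- ifelse(mod_c > 0, observed$data$value / mod_c, NA_real_)
  if (all(is.na(ratio))) {
    ratio_f <- rep(1, length(tf))
  } else if (sum(!is.na(ratio)) == 1L) {
    ratio_f <- rep(ratio[!is.na(ratio)], length(tf))
  } else {
    ok <- !is.na(ratio)
    ratio_f <- approx(tc[ok], ratio[ok], xout = tf, rule = 2)$y
  }
  val <- modeled$data$value * ratio_f
  val[modeled$data$value == 0] <- 0
  stream_ts(modeled$site_id, "par_calcLatSw", modeled$data$DateTime, val,
            resolution = modeled$resolution)
}

#' Hydraulic-geometry power laws
#'
#' At-a-station hydraulic geometry: mean reach depth `c * Q^f` (m) and mean
#' velocity `k * Q^m` (m s-1), with discharge `Q` in m3 s-1. Nonpositive
#' discharge has no defined depth/velocity and yields `NA` (the day is later
#' excluded by the positive-flow filter).
#'
#' @param discharge Discharge, m3 s-1.
#' @param coefs Named coefficients: `c(c = , f = )` for depth,
#'   `c(k = , m = )` for velocity.
#' @return Depth (m) or velocity (m s-1); `NA` where `discharge <= 0`.
#' @export
depth_from_discharge <- function(discharge, coefs) {
  out <- ifelse(is.na(discharge) | discharge <= 0, NA_real_,
                coefs[["c"]] * discharge^coefs[["f"]])
  as.numeric(out)
}

#' @rdname depth_from_discharge
#' @export
velocity_from_discharge <- function(discharge, coefs) {
  out <- ifelse(is.na(discharge) | discharge <= 0, NA_real_,
                coefs[["k"]] * discharge^coefs[["m"]])
  as.numeric(out)
}

#' Convert discharge from ft3 s-1 to m3 s-1
#'
#' Raw gauge discharge arrives in ft3 s-1; all derived quantities (power
#' laws, daily means) use m3 s-1.
#'
#' @param discharge_cfs Discharge, ft3 s-1.
#' @return Discharge, m3 s-1.
#' @export
cfs_to_cms <- function(discharge_cfs) {
  discharge_cfs * 0.0283168
}

#' Percent oxygen saturation
#'
#' `100 * doobs / dosat`.
#'
#' @param doobs Observed dissolved oxygen, mg L-1.
#' @param dosat Saturation concentration, mg L-1 (> 0).
#' @return Percent saturation.
#' @export
percent_saturation <- function(doobs, dosat) {
  if (any(dosat <= 0, na.rm = TRUE)) stop("dosat must be > 0")
  100 * doobs / dosat
}

#' Metabolism date of a mean-solar instant
#'
#' Metabolism days run from 04:00 of date `d` through 03:59 of `d + 1` in
#' mean solar time, so an observation at mean-solar 03:30 on calendar date
#' `d` belongs to metabolism date `d - 1`.
#'
#' @param solar_time Mean solar time (`POSIXct`).
#' @return `Date` vector of metabolism dates.
#' @export
metab_date <- function(solar_time) {
  as.Date(solar_time - 4 * 3600, tz = "UTC")
}

#' Daily aggregation over metabolism-day windows
#'
#' Aggregates a UTC time series over 24-h windows from 04:00 to 03:59 mean
#' solar time. `mean` and `range` (max - min) use the available values in
#' each window; `count_positive_hours` returns the number of hours with value
#' > 0 (daylight hours when applied to PPFD), i.e. the count of positive
#' steps times the series resolution.
#'
#' @param ts A [stream_ts] with UTC timestamps.
#' @param statistic `"mean"`, `"range"`, or `"count_positive_hours"`.
#' @param longitude Site longitude, decimal degrees east, used for the
#'   mean-solar conversion that defines the windows.
#' @return `data.frame` with columns `date` (metabolism date) and `value`.
#' @export
daily_aggregate <- function(ts, statistic = c("mean", "range",
                                              "count_positive_hours"),
                            longitude) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ts, "stream_ts"))
  solar <- convert_UTC_to_solartime(ts$data$DateTime, longitude, "mean")
  date <- metab_date(solar)
  v <- ts$data$value
  f <- switch(statistic,
    mean = function(x) mean(x, na.rm = TRUE),
    range = function(x) if (all(is.na(x))) NA_real_ else
      diff(range(x, na.rm = TRUE)),
    count_positive_hours = function(x) sum(x > 0, na.rm = TRUE) *
      ts$resolution / 60)
  agg <- tapply(v, date, f)
  out <- data.frame(date = as.Date(names(agg)), value = as.numeric(agg))
  rownames(out) <- NULL
  out[is.nan(out$value), "value"] <- NA_real_
  out
}
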