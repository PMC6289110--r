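#' Configuration for a synthetic monitoring site
#'
#' Defines the generative conditions for a synthetic site whose true daily
#' rates are known: a temperate mid-order stream (mean depth ~0.5 m, median
#' K600 ~10 d-1, GPP roughly 2-8 and ER -4 to -12 g O2 m-2 d-1). Discharge
#' is lognormal AR(1) at the daily scale (smoothly interpolated within
#' days), water temperature has a diel sinusoid plus AR(1) noise, shortwave
#' radiation is clear-sky light attenuated by a beta-distributed daily cloud
#' factor, and true GPP is tied to realized daily light (productivity
#' proportional to mean PPFD) so clouds create realistic covariation. True
#' daily K600 follows a two-segment piecewise-linear function of ln(Q) with
#' optional daily deviations. Oxygen is simulated from the same trapezoid
#' state-space process the model assumes (per-step process noise, then
#' observation noise).
#'
#' @param seed Integer RNG seed.
#' @param n_days Number of complete metabolism days.
#' @param resolution_min Oxygen/temperature/discharge timestep, minutes
#'   (one of 5, 15, 30, 60).
#' @param latitude,longitude,altitude Site location (degrees, degrees, m).
#'   The default longitude (-90) puts mean solar time exactly 6 h behind
#'   UTC.
#' @param start_date First metabolism date.
#' @param lnQ_mean,lnQ_sd,lnQ_ar Daily ln-discharge AR(1) process
#'   (stationary mean/sd, autocorrelation); discharge in m3 s-1.
#' @param temp_mean,temp_diel_amp,temp_noise_sd Water temperature model,
#'   degC (diel amplitude is peak-to-trough).
#' @param cloud_shape1,cloud_shape2 Beta parameters of the daily cloud
#'   attenuation factor.
#' @param k600_base Median K600, d-1.
#' @param k600_slopes Two piecewise slopes of ln(K600) vs ln(Q) below/above
#'   the median ln(Q).
#' @param sigma_K600_daily_true SD of daily K600 deviations from the
#'   piecewise relationship, d-1 (natural scale).
#' @param gpp_base,gpp_sd Mean daily GPP and its day-to-day noise sd,
#'   g O2 m-2 d-1.
#' @param gpp_light_tied Tie true GPP to realized daily light
#'   (default TRUE).
#' @param er_base,er_sd Mean daily ER and noise sd, g O2 m-2 d-1.
#' @param sigma_obs,sigma_proc Observation error sd (mg L-1) and per-step
#'   process error sd (mg L-1).
#' @param gaps List of gap injections, each
#'   `list(variable =, day =, start_hour =, duration_hours =)` with
#'   `variable` in doobs/wtr/disch/baro/sw, `day` an index into the
#'   metabolism dates and `start_hour` a mean-solar clock hour on that
#'   calendar date.
#' @param depth_coefs,veloc_coefs Hydraulic-geometry coefficients (see
#'   [site_record]).
#' @return A `synthetic_site_config` list.
#' @export
synthetic_site_config <- function(seed = 42, n_days = 14,
                                  resolution_min = 15,
                                  latitude = 39.5, longitude = -90,
                                  altitude = 210,
                                  start_date = as.Date("2015-06-15"),
                                  lnQ_mean = log(3), lnQ_sd = 0.25,
                                  lnQ_ar = 0.8,
                                  temp_mean = 18, temp_diel_amp = 2.5,
                                  temp_noise_sd = 0.1,
                                  cloud_shape1 = 8, cloud_shape2 = 2,
                                  k600_base = 10, k600_slopes = c(0.4, 0.1),
                                  sigma_K600_daily_true = 0.2,
                                  gpp_base = 5, gpp_sd = 0.5,
                                  gpp_light_tied = TRUE,
                                  er_base = -8, er_sd = 1,
                                  sigma_obs = 0.05, sigma_proc = 0.02,
                                  gaps = list(),
                                  depth_coefs = c(c = 0.4, f = 0.25),
                                  veloc_coefs = c(k = 0.35, m = 0.25)) {
  cfg <- as.list(environment())
  if (!resolution_min %in% c(5, 15, 30, 60))
    stop("resolution_min must be one of 5, 15, 30, 60")
  if (any(c(lnQ_sd, temp_noise_sd < 0, sigma_obs < 0, sigma_proc < 0,
            gpp_sd < 0, er_sd < 0) < 0))
    stop("all scale parameters must be >= 0")
  structure(cfg, class = "synthetic_site_config")
}

ar1 <- function(n, sd, ar) {
  if (n == 1L) return(rnorm(1, 0, sd))
  x <- numeric(n)
  x[1L] <- rnorm(1, 0, sd)
  innov <- rnorm(n - 1L, 0, sd * sqrt(1 - ar^2))
  for (i in 2:n) x[i] <- ar * x[i - 1L] + innov[i - 1L]
  x
}

#' Generate a synthetic site
#'
#' Produces raw sensor/reanalysis-style series (oxygen, water temperature,
#' discharge in ft3 s-1 at the fine resolution; barometric pressure and
#' shortwave radiation hourly) with UTC timestamps, plus the full latent
#' truth. The oxygen series is simulated from the trapezoid state-space
#' process using forcing variables derived with the same functions the
#' estimation pipeline uses, so with zero noise and no gaps the pipeline
#' reproduces the generator's path exactly.
#'
#' @param config A [synthetic_site_config].
#' @return List with `site` (a [site_record]), `raws` (named list of
#'   [stream_ts]: `doobs`, `wtr`, `disch`, `baro`, `sw`, gaps applied), and
#'   `truth` (list: `daily` truth table with `date`, `GPP`, `ER`, `K600`,
#'   `lnQ`; `path` latent oxygen; `input` the clean gap-free model-input
#'   table; `pool` the true piecewise nodes; `sigma_obs`, `sigma_proc`;
#'   `config`).
#' @export
generate_site <- function(config) {
  stopifnot(inherits(config, "synthetic_site_config"))
  cfg <- config
  set.seed(cfg$seed)
  site <- site_record("synth01", cfg$latitude, cfg$longitude, cfg$altitude,
                      cfg$depth_coefs, cfg$veloc_coefs)
  res_s <- cfg$resolution_min * 60
  off <- cfg$longitude * 240
  dates <- cfg$start_date + 0:(cfg$n_days - 1L)

  start_solar <- as.POSIXct(paste(cfg$start_date, "04:00:00"), tz = "UTC")
  ns <- cfg$n_days * 1440L / cfg$resolution_min
  solar_t <- start_solar + (seq_len(ns) - 1L) * res_s
  utc_t <- solar_t - off
  date_pt <- metab_date(solar_t)

  # hourly reanalysis-style grid, padded one hour past the fine span
  utc_h <- seq(utc_t[1L] - 3600, utc_t[ns] + 3600, by = 3600)
  solar_h <- convert_UTC_to_solartime(utc_h, cfg$longitude, "mean")

  # discharge: daily lognormal AR(1), interpolated at day midpoints
  lnQ_daily <- cfg$lnQ_mean + ar1(cfg$n_days, cfg$lnQ_sd, cfg$lnQ_ar)
  mid <- as.numeric(as.POSIXct(paste(dates, "16:00:00"), tz = "UTC"))
  lnQ_pt <- approx(mid, lnQ_daily, xout = as.numeric(solar_t), rule = 2)$y
  Q_cms <- exp(lnQ_pt)
  if (all(Q_cms <= 0)) stop("configuration yields nonpositive discharge")

  hour_solar <- as.numeric(solar_t) %% 86400 / 3600
  wtr <- cfg$temp_mean +
    cfg$temp_diel_amp / 2 * sin(2 * pi * (hour_solar - 11) / 24) +
    ar1(ns, cfg$temp_noise_sd, 0.9)

  baro_h <- calc_air_pressure(cfg$altitude) + ar1(length(utc_h), 40, 0.95)

  cloud <- rbeta(cfg$n_days, cfg$cloud_shape1, cfg$cloud_shape2)
  date_h <- metab_date(solar_h)
  cloud_h <- cloud[match(date_h, dates)]
  cloud_h[is.na(cloud_h)] <- mean(cloud)
  app_h <- convert_UTC_to_solartime(utc_h, cfg$longitude, "apparent")
  sw_h <- calc_light(app_h, cfg$latitude) / 2.114 * cloud_h

  # derived forcings on the fine grid, via the estimation pipeline's own
  # functions so the generative process and the fitted model agree
  baro_pt <- approx(as.numeric(utc_h), baro_h, xout = as.numeric(utc_t),
                    rule = 2)$y
  dosat <- as.numeric(calc_DO_sat(wtr, baro_pt))
  app_pt <- convert_UTC_to_solartime(utc_t, cfg$longitude, "apparent")
  par_lat <- stream_ts(site$site_id, "par_calcLat", utc_t,
                       calc_light(app_pt, cfg$latitude), cfg$resolution_min)
  par_sw <- stream_ts(site$site_id, "par_calcSw", utc_h,
                      convert_SW_to_PAR(sw_h), 60)
  light <- calc_light_merged(par_lat, par_sw)$data$value
  depth <- depth_from_discharge(Q_cms, cfg$depth_coefs)

  # daily truth
  light_d <- as.numeric(tapply(light, date_pt, mean))
  gpp_scale <- if (cfg$gpp_light_tied && mean(light_d) > 0)
    light_d / mean(light_d) else rep(1, cfg$n_days)
  GPP_d <- pmax(0.5, cfg$gpp_base * gpp_scale + rnorm(cfg$n_days, 0,
                                                      cfg$gpp_sd))
  ER_d <- cfg$er_base + rnorm(cfg$n_days, 0, cfg$er_sd)
  midQ <- median(lnQ_daily)
  lnK_fun <- function(lnq) {
    log(cfg$k600_base) + ifelse(lnq <= midQ,
                                cfg$k600_slopes[1L] * (lnq - midQ),
                                cfg$k600_slopes[2L] * (lnq - midQ))
  }
  K600_d <- pmax(0.1, exp(lnK_fun(lnQ_daily)) +
                   rnorm(cfg$n_days, 0, cfg$sigma_K600_daily_true))

  # latent oxygen over the whole contiguous grid (per-step day parameters)
  di <- match(date_pt, dates)
  kcoef <- (schmidt_number_O2(wtr) / 600)^-0.5
  lfrac <- light / light_d[di]
  lfrac[!is.finite(lfrac)] <- 0
  k_pt <- K600_d[di] * kcoef
  c_pt <- (GPP_d[di] * lfrac + ER_d[di]) / depth + k_pt * dosat
  dt <- cfg$resolution_min / 1440
  eps <- rnorm(ns - 1L, 0, cfg$sigma_proc)
  path <- numeric(ns)
  path[1L] <- dosat[1L]
  for (i in seq_len(ns - 1L)) {
    denom <- 1 + dt * k_pt[i + 1L] / 2
    a <- (1 - dt * k_pt[i] / 2) / denom
    b <- dt / 2 * (c_pt[i] + c_pt[i + 1L]) / denom
    path[i + 1L] <- a * path[i] + b + eps[i]
  }
  obs <- path + rnorm(ns, 0, cfg$sigma_obs)

  input <- data.frame(solar.time = solar_t, date = date_pt, DO.obs = obs,
                      DO.sat = dosat, depth = depth, temp.water = wtr,
                      light = light, discharge = Q_cms)
  attr(input, "resolution") <- cfg$resolution_min
  class(input) <- c("metab_input", "data.frame")

  raws <- list(
    doobs = stream_ts(site$site_id, "doobs_nwis", utc_t, obs,
                      cfg$resolution_min),
    wtr = stream_ts(site$site_id, "wtr_nwis", utc_t, wtr,
                    cfg$resolution_min),
    disch = stream_ts(site$site_id, "disch_nwis", utc_t,
                      Q_cms / 0.0283168, cfg$resolution_min),
    baro = stream_ts(site$site_id, "baro_nldas", utc_h, baro_h, 60),
    sw = stream_ts(site$site_id, "sw_nldas", utc_h, sw_h, 60))

  for (g in cfg$gaps) {
    v <- g$variable
    if (!v %in% names(raws)) stop("unknown gap variable ", v)
    ts <- raws[[v]]
    sol <- convert_UTC_to_solartime(ts$data$DateTime, cfg$longitude, "mean")
    t0 <- as.POSIXct(paste(dates[g$day], sprintf("%02d:00:00",
                                                 g$start_hour)),
                     tz = "UTC")
    drop <- sol >= t0 & sol < t0 + g$duration_hours * 3600
    raws[[v]] <- stream_ts(ts$site_id, ts$variable,
                           ts$data$DateTime[!drop], ts$data$value[!drop],
                           ts$resolution)
  }

  grid_lnQ <- range(lnQ_daily)
  truth_nodes <- seq(grid_lnQ[1L], grid_lnQ[2L], length.out = 5L)
  list(site = site, raws = raws,
       truth = list(
         daily = data.frame(date = dates, GPP = GPP_d, ER = ER_d,
                            K600 = K600_d, lnQ = lnQ_daily),
         path = data.frame(DateTime = utc_t, solar.time = solar_t,
                           O2 = path),
         input = input,
         pool = list(node_lnQ = truth_nodes,
                     node_lnK600 = lnK_fun(truth_nodes)),
         sigma_obs = cfg$sigma_obs, sigma_proc = cfg$sigma_proc,
         config = cfg))
}

#' Compare a fit against synthetic truth
#'
#' Per-parameter recovery report over the days present in both the fit and
#' the truth table: bias and RMSE of the posterior medians, RMSE relative
#' to the mean true magnitude, and empirical coverage of the 95% credible
#' intervals.
#'
#' @param fit A `metab_fit`.
#' @param truth The `truth` element of [generate_site] output (or any list
#'   with a `daily` truth table).
#' @return data.frame with one row per parameter (GPP, ER, K600): `bias`,
#'   `rmse`, `rel_rmse`, `coverage95`, `n_days`.
#' @export
truth_comparison <- function(fit, truth) {
  td <- truth$daily
  common <- as.Date(intersect(fit$dates, td$date), origin = "1970-01-01")
  if (length(common) == 0L) stop("no overlapping dates")
  rows <- lapply(c("GPP", "ER", "K600"), function(p) {
    est <- fit$daily[fit$daily$parameter == p, ]
    est <- est[match(common, est$date), ]
    tru <- td[[p]][match(common, td$date)]
    err <- est$q50 - tru
    data.frame(parameter = p,
               bias = mean(err),
               rmse = sqrt(mean(err^2)),
               rel_rmse = sqrt(mean(err^2)) / mean(abs(tru)),
               coverage95 = mean(tru >= est$q2.5 & tru <= est$q97.5),
               n_days = length(common), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
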