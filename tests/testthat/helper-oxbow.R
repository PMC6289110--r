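# shared fixtures and independent oracles

# a hand-built metabolism day: n points at `res` minutes, sinusoidal light,
# constant or supplied forcings; all rows share one date so the full span
# (including an optional closing 04:00 point) integrates as one day
make_day_input <- function(n = 96, res = 15, depth = 0.5, temp = 20,
                           dosat = 9.09, light = NULL,
                           obs = NA_real_, date = as.Date("2015-06-15")) {
  solar <- as.POSIXct(paste(date, "04:00:00"), tz = "UTC") +
    (seq_len(n) - 1L) * res * 60
  hour <- as.numeric(solar) %% 86400 / 3600
  if (is.null(light))
    light <- 1500 * pmax(0, sin(pi * (hour - 6) / 14)) * (hour > 6 & hour < 20)
  d <- data.frame(solar.time = solar, date = date,
                  DO.obs = rep_len(obs, n), DO.sat = rep_len(dosat, n),
                  depth = rep_len(depth, n), temp.water = rep_len(temp, n),
                  light = rep_len(light, n),
                  discharge = rep_len(2.5, n))
  attr(d, "resolution") <- res
  class(d) <- c("metab_input", "data.frame")
  d
}

# independent fine-step integrator: classical RK4 at `refine` x finer steps
# on the oxygen balance with linearly interpolated forcings
rk4_oracle <- function(gpp, er, k600, day, init, refine = 100) {
  n <- nrow(day)
  dt <- attr(day, "resolution") / 1440
  tt <- (seq_len(n) - 1L) * dt
  ml <- mean(day$light)
  lf <- if (is.finite(ml) && ml > 0) day$light / ml else rep(0, n)
  f_lf <- approxfun(tt, lf, rule = 2)
  f_iz <- approxfun(tt, 1 / day$depth, rule = 2)
  f_kc <- approxfun(tt, (schmidt_number_O2(day$temp.water) / 600)^-0.5,
                    rule = 2)
  f_os <- approxfun(tt, day$DO.sat, rule = 2)
  dOdt <- function(s, O)
    (gpp * f_lf(s) + er) * f_iz(s) + k600 * f_kc(s) * (f_os(s) - O)
  h <- dt / refine
  out <- numeric(n)
  out[1L] <- O <- init
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq_len(refine)) {
      k1 <- dOdt(s, O)
      k2 <- dOdt(s + h / 2, O + h / 2 * k1)
      k3 <- dOdt(s + h / 2, O + h / 2 * k2)
      k4 <- dOdt(s + h, O + h * k3)
      O <- O + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      s <- s + h
    }
    out[i + 1L] <- O
  }
  out
}

# reduced MCMC settings for test-speed fits
fast_mcmc <- function(chains = 2, warmup = 300, saved = 250, thin = 5) {
  mcmc_spec(chains = chains, warmup = warmup, saved = saved, thin = thin)
}

# independently coded confidence oracle: counts band memberships per metric
# (1 = Low band, 2 = Medium band, 3 = High band) and applies the
# worst-band rule; written as a lookup rather than threshold cascades
confidence_oracle <- function(rh, kr, pg, pe) {
  band <- function(x, lo, hi) if (x > lo) 1L else if (x < hi) 3L else 2L
  bands <- c(band(rh, 1.2, 1.2), band(kr, 50, 15),
             band(pg, 50, 25), band(pe, 50, 25))
  c("Low", "Medium", "High")[min(bands)]
}
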