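#' Schmidt number of oxygen in fresh water
#'
#' Third-order polynomial in water temperature,
#' `Sc = 1568 - 86.04 T + 2.142 T^2 - 0.0216 T^3` (freshwater O2
#' parameterization; fit range 0-40 degC). Decreasing in temperature;
#' equals 600 near 17.6 degC.
#'
#' @param temp_water Water temperature, degC.
#' @return Dimensionless Schmidt number.
#' @export
schmidt_number_O2 <- function(temp_water) {
  if (any(temp_water < 0 | temp_water > 40, na.rm = TRUE))
    warning("temperature outside the Schmidt-number fit range [0, 40] C")
  1568 - 86.04 * temp_water + 2.142 * temp_water^2 - 0.0216 * temp_water^3
}

#' Convert K600 to the oxygen-specific gas exchange coefficient
#'
#' Schmidt-number scaling `KO2 = K600 * (Sc_O2 / 600)^-0.5`. At the
#' temperature where `Sc_O2 = 600`, `KO2 = K600` exactly.
#'
#' @param K600 Gas exchange rate coefficient normalized to Sc = 600, d-1
#'   (>= 0).
#' @param temp_water Water temperature, degC.
#' @return KO2, d-1.
#' @export
K600_to_KO2 <- function(K600, temp_water) {
  if (any(K600 < 0, na.rm = TRUE)) stop("K600 must be >= 0")
  K600 * (schmidt_number_O2(temp_water) / 600)^-0.5
}

# per-day model tensors for the likelihood and simulator:
# lfrac_i = PPFD_i / mean(PPFD) (0 if the daily mean is not > 0),
# invz_i = 1/depth_i, kcoef_i = (Sc/600)^-0.5, dt in days
day_tensors <- function(input, dates = NULL) {
  res <- attr(input, "resolution")
  if (is.null(res)) stop("input lacks a resolution attribute")
  dt <- res / 1440
  if (is.null(dates)) dates <- sort(unique(input$date))
  lapply(dates, function(d) {
    rows <- input[input$date == d, , drop = FALSE]
    if (nrow(rows) < 2L) stop("day ", d, " has fewer than 2 rows")
    step <- diff(as.numeric(rows$solar.time)) / 86400
    if (any(abs(step - dt) > 1e-9))
      stop("timestep is not uniform on day ", d)
    if (any(!is.na(rows$depth) & rows$depth <= 0))
      stop("nonpositive depth on day ", d)
    mean_light <- mean(rows$light, na.rm = TRUE)
    lfrac <- if (is.finite(mean_light) && mean_light > 0)
      rows$light / mean_light else rep(0, nrow(rows))
    qbar <- mean(rows$discharge, na.rm = TRUE)
    list(date = d, n = nrow(rows), dt = dt,
         obs = rows$DO.obs,
         lfrac = lfrac,
         invz = 1 / rows$depth,
         kcoef = (schmidt_number_O2(rows$temp.water) / 600)^-0.5,
         osat = rows$DO.sat,
         temp_mean = mean(rows$temp.water, na.rm = TRUE),
         lnQ = if (is.finite(qbar) && qbar > 0) log(qbar) else NA_real_)
  })
}

# trapezoid step coefficients O_{i+1} = a_i O_i + b_i (R mirror of the
# compiled core, used for the explicit-states density and in tests)
trap_coefs <- function(gpp, er, k600, lfrac, invz, kcoef, osat, dt) {
  k <- k600 * kcoef
  cc <- (gpp * lfrac + er) * invz + k * osat
  n <- length(k)
  denom <- 1 + dt * k[-1L] / 2
  list(a = (1 - dt * k[-n] / 2) / denom,
       b = dt / 2 * (cc[-n] + cc[-1L]) / denom)
}

#' Simulate one day of the diel oxygen balance
#'
#' Integrates the oxygen mass balance
#' `dO/dt = GPP/z * PPFD/mean(PPFD) + ER/z + KO2 * (Osat - O)` with the
#' trapezoid rule: the gas-exchange term is implicit in `O_{i+1}` and each
#' step is solved in closed form (no iterative solver). The GPP term is zero
#' on days with no positive light. Optional Gaussian process noise is added
#' after each step.
#'
#' @param gpp,er,k600 Daily parameters: GPP and ER in g O2 m-2 d-1 (ER
#'   typically negative), K600 in d-1 (>= 0).
#' @param day_input One day of a `metab_input` table (uniform timestep;
#'   columns `solar.time`, `DO.obs`, `DO.sat`, `depth`, `temp.water`,
#'   `light`).
#' @param init_O Initial oxygen state, mg L-1; defaults to the day's first
#'   non-missing observation.
#' @param proc_noise Optional numeric vector of per-step process deviations
#'   (length `nrow(day_input) - 1`), added after each trapezoid step.
#' @return Numeric vector of modeled oxygen (mg L-1) on the day's
#'   timestamps. A warning is raised if the path goes negative.
#' @export
simulate_day <- function(gpp, er, k600, day_input, init_O = NULL,
                         proc_noise = NULL) {
  td <- day_tensors(day_input, dates = unique(day_input$date)[1L])[[1L]]
  if (is.null(init_O)) {
    if (all(is.na(td$obs))) stop("no observation to initialize the day")
    init_O <- td$obs[which(!is.na(td$obs))[1L]]
  }
  path <- .ox_day_path(gpp, er, k600, td$lfrac, td$invz, td$kcoef, td$osat,
                       td$dt, init_O, proc_noise)
  if (any(path < 0)) warning("modeled oxygen went negative")
  path
}

#' State-space log density of the oxygen model
#'
#' The model fits both oxygen concentrations and stepwise concentration
#' changes: latent oxygen states follow the deterministic trapezoid update
#' plus Gaussian process error (sd `sigma_proc`, per step), and observations
#' equal the states plus Gaussian observation error (sd `sigma_obs`). Each
#' day's initial state is its first oxygen observation; gas exchange always
#' uses the modeled state, not the observations.
#'
#' With `states = NULL` the latent states are marginalized analytically (the
#' update is linear in oxygen, so the model is linear-Gaussian given the
#' parameters) and the function returns the marginal log likelihood of the
#' observations, day by day, via a scalar Kalman filter. Supplying explicit
#' `states` returns the joint log density of states and observations.
#' Supplying `priors` (and a node `pool`) adds the log prior, giving the log
#' posterior density up to a constant.
#'
#' @param params data.frame with columns `date`, `GPP`, `ER`, `K600`, one
#'   row per valid day.
#' @param errors List with `sigma_obs` and `sigma_proc` (mg L-1, > 0).
#' @param input A `metab_input` table covering the dates in `params`.
#' @param states Optional list of per-day latent state vectors (same order
#'   as `params$date`, same length as each day's rows).
#' @param priors Optional [prior_spec]; requires `pool`.
#' @param pool Optional [k600_pool] for the hierarchical K600 terms.
#' @return Log density (scalar); `-Inf` for invalid parameter values.
#' @export
state_space_logdensity <- function(params, errors, input, states = NULL,
                                   priors = NULL, pool = NULL) {
  if (errors$sigma_obs <= 0 || errors$sigma_proc < 0) return(-Inf)
  tds <- day_tensors(input, dates = params$date)
  q2 <- errors$sigma_proc^2
  r2 <- errors$sigma_obs^2
  ll <- 0
  for (i in seq_along(tds)) {
    td <- tds[[i]]
    if (is.null(states)) {
      ll <- ll + .ox_day_loglik(params$GPP[i], params$ER[i], params$K600[i],
                                td$lfrac, td$invz, td$kcoef, td$osat,
                                td$obs, td$dt, q2, r2)
    } else {
      s <- states[[i]]
      if (length(s) != td$n) stop("states[[", i, "]] has wrong length")
      ab <- trap_coefs(params$GPP[i], params$ER[i], params$K600[i],
                       td$lfrac, td$invz, td$kcoef, td$osat, td$dt)
      pred <- ab$a * s[-td$n] + ab$b
      ll <- ll + sum(dnorm(s[-1L], pred, errors$sigma_proc, log = TRUE))
      obs_idx <- which(!is.na(td$obs))
      obs_idx <- obs_idx[obs_idx > 1L]
      ll <- ll + sum(dnorm(td$obs[obs_idx], s[obs_idx], errors$sigma_obs,
                           log = TRUE))
    }
  }
  if (!is.finite(ll)) return(-Inf)
  if (!is.null(priors)) {
    if (is.null(pool)) stop("priors require a pool")
    lnQ <- vapply(tds, `[[`, numeric(1), "lnQ")
    ll <- ll + log_prior_all(params, pool, errors, priors, lnQ)
  }
  ll
}
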