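test_that("Schmidt number polynomial evaluates exactly and decreases with temperature", {
  expect_equal(schmidt_number_O2(20), 531.2, tolerance = 0.5 / 531.2)
  expect_equal(schmidt_number_O2(17.5), 600, tolerance = 0.02)
  expect_lt(schmidt_number_O2(30), schmidt_number_O2(10))
})

test_that("K600 to KO2 scaling is exact at Sc = 600 and matches direct evaluation", {
  t_star <- uniroot(function(T) schmidt_number_O2(T) - 600, c(10, 25),
                    tol = 1e-12)$root
  expect_equal(K600_to_KO2(7.3, t_star), 7.3, tolerance = 1e-9)
  expect_equal(K600_to_KO2(10, 20), 10.63, tolerance = 1e-3)
  expect_equal(K600_to_KO2(0, 15), 0)
  expect_error(K600_to_KO2(-1, 15), ">= 0")
})

test_that("with high gas exchange and no metabolism the path converges to saturation", {
  day <- make_day_input(n = 96, light = 0)
  p <- simulate_day(0, 0, 30, day, init_O = 6)
  expect_lt(abs(p[length(p)] - day$DO.sat[1]), 1e-3)
})

test_that("with no gas exchange the daily drift is (GPP+ER)/depth exactly", {
  # 97 points so the steps span exactly one day; constant light
  day <- make_day_input(n = 97, light = 800, depth = 0.8)
  p <- simulate_day(4, -6.5, 0, day, init_O = 8)
  expect_equal(p[97] - p[1], (4 - 6.5) / 0.8, tolerance = 1e-12)
})

test_that("the trapezoid update is time-reversible without gas exchange", {
  day <- make_day_input(n = 96)
  p <- simulate_day(5, -7, 0, day, init_O = 8.5)
  # backward recursion: with K600 = 0 each step adds dt/2*(c_i + c_{i+1})
  dt <- attr(day, "resolution") / 1440
  lfrac <- day$light / mean(day$light)
  cc <- (5 * lfrac - 7) / day$depth
  back <- p[96]
  for (i in 95:1) back <- back - dt / 2 * (cc[i] + cc[i + 1])
  expect_equal(back, 8.5, tolerance = 1e-12)
})

test_that("gas exchange pushes oxygen toward saturation at every step", {
  day <- make_day_input(n = 96, light = 0)
  for (init in c(5, 12)) {
    p <- simulate_day(0, 0, 8, day, init_O = init)
    expect_true(all(sign(diff(p)) == sign(day$DO.sat[1] - p[-96])))
  }
})

test_that("trapezoid paths match the fine-step integrator on a full diel case", {
  day <- make_day_input(n = 96, depth = 0.5)
  p <- simulate_day(5, -8, 15, day, init_O = 8.8)
  o <- rk4_oracle(5, -8, 15, day, init = 8.8)
  expect_lt(max(abs(p - o)), 0.02)
})

test_that("process noise enters after each step and nonpositive depth errors", {
  day <- make_day_input(n = 48, res = 30)
  eps <- rep(0.01, 47)
  p0 <- simulate_day(3, -6, 10, day, init_O = 9)
  p1 <- simulate_day(3, -6, 10, day, init_O = 9, proc_noise = eps)
  expect_gt(min((p1 - p0)[-1]), 0)
  expect_equal(p1[1], p0[1])
  expect_error(simulate_day(3, -6, 10, day, init_O = 9,
                            proc_noise = rep(0, 5)), "length")
  bad <- day; bad$depth[10] <- -0.1
  expect_error(simulate_day(3, -6, 10, bad), "depth")
})

test_that("the state-space density peaks on the deterministic path", {
  day <- make_day_input(n = 48, res = 30)
  p <- simulate_day(5, -8, 12, day, init_O = 9)
  day$DO.obs <- p
  params <- data.frame(date = day$date[1], GPP = 5, ER = -8, K600 = 12)
  err <- list(sigma_obs = 0.05, sigma_proc = 1e-6)
  ll_match <- state_space_logdensity(params, err, day)
  off <- day; off$DO.obs <- p + rnorm(48, 0, 0.2)
  expect_gt(ll_match, state_space_logdensity(params, err, off))
})

test_that("doubling all residuals lowers the joint density by the closed-form amount", {
  day <- make_day_input(n = 4, res = 15)
  gpp <- 4; er <- -7; k600 <- 9
  det <- simulate_day(gpp, er, k600, day, init_O = 9)
  r <- c(0, 0.08, -0.05, 0.12)       # process deviations from the path
  e <- c(0, -0.03, 0.06, -0.02)      # observation residuals
  # residuals of (det + s*r) relative to the one-step predictions scale
  # linearly in s because the update is linear and det solves it exactly
  params <- data.frame(date = day$date[1], GPP = gpp, ER = er, K600 = k600)
  err <- list(sigma_obs = 0.1, sigma_proc = 0.15)
  ll <- function(s) {
    states <- det + s * r
    d <- day; d$DO.obs <- states + s * e
    state_space_logdensity(params, err, d, states = list(states))
  }
  dt <- attr(day, "resolution") / 1440
  lfrac <- day$light / mean(day$light)
  kc <- (schmidt_number_O2(day$temp.water) / 600)^-0.5
  k <- k600 * kc
  cc <- (gpp * lfrac + er) / day$depth + k * day$DO.sat
  a <- (1 - dt * k[-4] / 2) / (1 + dt * k[-1] / 2)
  proc_resid <- r[-1] - a * r[-4]
  quad <- sum(proc_resid^2) / (2 * 0.15^2) + sum(e[-1]^2) / (2 * 0.1^2)
  expect_equal(ll(1) - ll(2), 3 * quad, tolerance = 1e-8)
})

test_that("the marginal density is invariant to permuting days", {
  g <- generate_site(synthetic_site_config(seed = 5, n_days = 3))
  input <- g$truth$input
  td <- g$truth$daily
  params <- data.frame(date = td$date, GPP = td$GPP, ER = td$ER,
                       K600 = td$K600)
  err <- list(sigma_obs = 0.05, sigma_proc = 0.02)
  ll1 <- state_space_logdensity(params, err, input)
  ll2 <- state_space_logdensity(params[c(3, 1, 2), ], err, input)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("marginalized and explicit-states densities agree when process error vanishes", {
  day <- make_day_input(n = 24, res = 60)
  p <- simulate_day(5, -8, 10, day, init_O = 9)
  day$DO.obs <- p + c(0, rnorm(23, 0, 0.05))
  params <- data.frame(date = day$date[1], GPP = 5, ER = -8, K600 = 10)
  err <- list(sigma_obs = 0.05, sigma_proc = 0)
  # with sigma_proc = 0 the latent path is the deterministic one
  marg <- state_space_logdensity(params, err, day)
  obs_only <- sum(dnorm(day$DO.obs[-1], p[-1], 0.05, log = TRUE))
  expect_equal(marg, obs_only, tolerance = 1e-9)
})
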