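test_that("node grids bracket the observed discharge range at 0.2-ln spacing", {
  g1 <- build_nodes(c(1.5, 1.5, 1.5))
  expect_length(g1, 2L)
  expect_true(min(g1) <= 1.5 && max(g1) >= 1.5)

  lnq <- c(0.07, 1.30)  # range 1.23
  g2 <- build_nodes(lnq)
  expect_length(g2, 8L)  # ceil(1.23/0.2) + 1
  expect_true(all(abs(diff(g2) - 0.2) < 1e-9))
  expect_lte(min(g2), min(lnq))
  expect_gte(max(g2), max(lnq))

  expect_length(build_nodes(c(2.0, 2.15)), 2L)
})

test_that("piecewise prediction interpolates between bracketing nodes", {
  pool <- k600_pool(c(1.0, 1.2, 1.4), c(2.0, 2.4, 2.1), 0.2)
  expect_equal(piecewise_predict(1.2, pool), 2.4)
  expect_equal(piecewise_predict(1.1, pool), mean(c(2.0, 2.4)))
  # a quarter of the way into the second segment
  expect_equal(piecewise_predict(1.25, pool), 2.325)
})

test_that("split R-hat and n_eff behave on iid, separated, and degenerate chains", {
  set.seed(99)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(iid), 1.01)
  expect_equal(n_eff(iid), 4000, tolerance = 0.2)

  sep <- cbind(rnorm(500, -5), rnorm(500, 5))
  expect_gt(rhat(sep), 1.2)
  expect_warning(r1 <- rhat(matrix(3, 100, 4)), "degenerate")
  expect_equal(r1, 1)
  expect_error(rhat(matrix(1, 10, 1)), "2 chains")
})

test_that("n_eff shrinks for autocorrelated chains, consistent with an external estimator", {
  skip_if_not_installed("coda")
  set.seed(7)
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.8), 1000)))
  ne <- n_eff(ar)
  expect_lt(ne, 1500)  # iid would be 4000
  ne_coda <- sum(vapply(seq_len(4), function(j)
    as.numeric(coda::effectiveSize(ar[, j])), numeric(1)))
  expect_equal(ne, ne_coda, tolerance = 0.5)
})

test_that("preliminary unpooled fit recovers a constant K600 and hands off the hyperprior scale", {
  g <- generate_site(synthetic_site_config(seed = 21, n_days = 6,
                                           k600_slopes = c(0, 0),
                                           sigma_K600_daily_true = 1e-8,
                                           sigma_proc = 0.01))
  pre <- fit_preliminary_nopool(g$truth$input, mcmc = fast_mcmc(), seed = 2)
  expect_gt(pre$median_K600, 8)
  expect_lt(pre$median_K600, 12)

  fit <- fit_metabolism(g$truth$input, mcmc = fast_mcmc(), seed = 2,
                        k600_median_prelim = 10)
  expect_equal(fit$config$skd_scale, 0.2)  # 2% of the median
})

test_that("posterior summaries are internally consistent and seed-reproducible", {
  g <- generate_site(synthetic_site_config(seed = 8, n_days = 5))
  fit1 <- fit_metabolism(g$truth$input, mcmc = fast_mcmc(), seed = 4,
                         k600_median_prelim = 10)
  fit2 <- fit_metabolism(g$truth$input, mcmc = fast_mcmc(), seed = 4,
                         k600_median_prelim = 10)
  expect_identical(fit1$daily, fit2$daily)
  expect_identical(fit1$overall, fit2$overall)

  for (tab in list(fit1$daily, fit1$nodes, fit1$overall)) {
    qs <- as.matrix(tab[, c("q2.5", "q25", "q50", "q75", "q97.5")])
    expect_true(all(diff(t(qs)) >= 0))
    expect_true(all(tab$n_eff <= fit1$mcmc$chains * fit1$mcmc$saved + 1e-9))
  }
  expect_setequal(unique(fit1$daily$date), g$truth$daily$date)
})

test_that("with a tiny pooling sd the daily K600 collapse onto the piecewise curve", {
  g <- generate_site(synthetic_site_config(seed = 13, n_days = 6))
  pr <- prior_spec(sigma_kd_scale = 1e-4)
  fit <- fit_metabolism(g$truth$input, priors = pr, mcmc = fast_mcmc(),
                        seed = 5, k600_median_prelim = 10)
  k50 <- fit$daily$q50[fit$daily$parameter == "K600"]
  pred <- exp(piecewise_predict(fit$lnQ, fit$pool))
  expect_lt(max(abs(k50 - pred)), 0.05)
})

test_that("zero-information data returns the GPP prior", {
  day <- make_day_input(n = 48, res = 30)
  set.seed(31)
  day$DO.obs <- 9 + rnorm(48, 0, 5)  # noise only, no diel signal
  pr <- prior_spec(sigma_obs_scale = 10)
  fit <- fit_metabolism(day, priors = pr,
                        mcmc = mcmc_spec(chains = 3, warmup = 500,
                                         saved = 300, thin = 5),
                        seed = 6, k600_median_prelim = 10)
  gpp <- fit$daily[fit$daily$parameter == "GPP", ]
  expect_lt(abs(gpp$mean - 3.1), 2 * gpp$sd)
})

test_that("parameter recovery improves as observation noise decreases", {
  rmse_at <- function(noise) {
    g <- generate_site(synthetic_site_config(seed = 17, n_days = 6,
                                             sigma_obs = noise))
    fit <- fit_metabolism(g$truth$input, mcmc = fast_mcmc(), seed = 7,
                          k600_median_prelim = 10)
    tc <- truth_comparison(fit, g$truth)
    mean(tc$rmse[tc$parameter %in% c("GPP", "ER")])
  }
  ladder <- vapply(c(0.02, 0.2, 1.0), rmse_at, numeric(1))
  expect_lt(ladder[1], ladder[3])
})

test_that("converged fits pass through the rerun rule; unconverged fits trigger a 2000/2000 refit", {
  g <- generate_site(synthetic_site_config(seed = 23, n_days = 3,
                                           resolution_min = 60))
  fit <- fit_metabolism(g$truth$input, mcmc = fast_mcmc(), seed = 8,
                        k600_median_prelim = 10)
  if (max(fit$overall$Rhat[fit$overall$parameter %in%
                             c("sigma_K600_daily", "sigma_proc")]) <= 1.2) {
    expect_identical(rerun_if_unconverged(fit, g$truth$input), fit)
  }
  # pathological run: 2 chains, almost no warmup or draws
  bad <- fit_metabolism(g$truth$input,
                        mcmc = mcmc_spec(chains = 2, warmup = 1, saved = 8,
                                         thin = 1),
                        seed = 9, k600_median_prelim = 10)
  keys <- bad$overall$Rhat[bad$overall$parameter %in%
                             c("sigma_K600_daily", "sigma_proc")]
  expect_gt(max(keys), 1.2)
  refit <- rerun_if_unconverged(bad, g$truth$input)
  expect_true(refit$rerun)
  expect_equal(refit$mcmc$warmup, 2000)
  expect_equal(refit$mcmc$saved, 2000)
})
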