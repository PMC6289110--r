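# Blockwise adaptive-Metropolis sampler for the metabolism posterior.
#
# The latent oxygen states are marginalized analytically (scalar Kalman
# filter in the compiled core), so the sampled space is only the daily
# parameters (GPP_d, ER_d, K600_d), the K600~Q node values, and the error
# SDs. Blocks: one 3-d block per day, one block for (nodes, ln sigma_K600),
# one for the log error SDs. Each block carries a Haario-style adapted
# proposal covariance (2.38^2/d * empirical covariance) with a
# Robbins-Monro-scaled step size targeting 0.3 acceptance; adaptation runs
# during warmup only, so the sampling phase is a fixed Markov kernel.

new_adapter <- function(scale0) {
  d <- length(scale0)
  list(d = d, n = 0, sum = rep(0, d), ss = matrix(0, d, d),
       lambda = 1, chol = diag(scale0, d, d), t = 0)
}

adapter_step <- function(ad) {
  sqrt(ad$lambda) * drop(crossprod(ad$chol, rnorm(ad$d)))
}

adapter_update <- function(ad, x, alpha) {
  ad$t <- ad$t + 1
  ad$lambda <- exp(log(ad$lambda) +
                     min(0.5, ad$t^-0.6) * (alpha - 0.3))
  ad$n <- ad$n + 1
  ad$sum <- ad$sum + x
  ad$ss <- ad$ss + tcrossprod(x)
  if (ad$n > 10 * ad$d && ad$t %% 50 == 0) {
    cv <- (ad$ss - tcrossprod(ad$sum) / ad$n) / (ad$n - 1)
    sigma <- 2.38^2 / ad$d * cv + diag(1e-10, ad$d)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (!is.null(ch)) ad$chol <- ch
  }
  ad
}

# one MCMC chain; returns a keep x P matrix of draws
run_metab_chain <- function(tds, model, priors, grid, skd_scale,
                            warm_sweeps, keep, thin, chain_seed,
                            init_k600) {
  set.seed(chain_seed)
  D <- length(tds)
  lnQ <- vapply(tds, `[[`, numeric(1), "lnQ")
  pooled <- model == "pooled"
  N <- if (pooled) length(grid) else 0L

  gpp <- rnorm(D, priors$gpp_mean, 0.5)
  er <- rnorm(D, priors$er_mean, 0.5)
  k600 <- init_k600 * exp(rnorm(D, 0, 0.2))
  sobs <- 0.05 * exp(rnorm(1, 0, 0.3))
  if (pooled) {
    eta <- rep(log(init_k600), N) + rnorm(N, 0, 0.05)
    skd <- skd_scale * exp(rnorm(1, 0, 0.3))
    sproc <- 0.05 * exp(rnorm(1, 0, 0.3))
  } else {
    eta <- numeric(0); skd <- NA_real_; sproc <- 0
  }
  q2 <- sproc^2; r2 <- sobs^2

  day_ll <- function(d, g, e, k, q2, r2) {
    td <- tds[[d]]
    .ox_day_loglik(g, e, k, td$lfrac, td$invz, td$kcoef, td$osat,
                   td$obs, td$dt, q2, r2)
  }
  kpred <- if (pooled) exp(approx(grid, eta, xout = lnQ)$y) else NULL
  day_lp <- function(d, g, e, k) {
    lp <- dnorm(g, priors$gpp_mean, priors$gpp_sd, log = TRUE) +
      dnorm(e, priors$er_mean, priors$er_sd, log = TRUE)
    if (pooled) {
      if (k < 0) return(-Inf)
      lp + dnorm(k, kpred[d], skd, log = TRUE)
    } else {
      if (k <= 0) return(-Inf)
      lp + dnorm(log(k), priors$k600_nopool_meanlog,
                 priors$k600_nopool_sdlog, log = TRUE) - log(k)
    }
  }
  node_lp <- function(eta, skd) {
    if (skd <= 0) return(-Inf)
    kp <- exp(approx(grid, eta, xout = lnQ)$y)
    dnorm(eta[1L], priors$k600_node_first_meanlog,
          priors$k600_node_first_sdlog, log = TRUE) +
      (if (N > 1L) sum(dnorm(diff(eta), 0, priors$k600_node_walk_sd,
                             log = TRUE)) else 0) +
      sum(dnorm(k600, kp, skd, log = TRUE)) +
      lp_halfnorm(skd, skd_scale) + log(skd)
  }
  hyper_sigma <- function(sobs, sproc) {
    lp <- lp_halfnorm(sobs, priors$sigma_obs_scale) + log(sobs)
    if (pooled)
      lp <- lp + lp_halfnorm(sproc, priors$sigma_proc_scale) + log(sproc)
    lp
  }

  Ld <- vapply(seq_len(D), function(d) day_ll(d, gpp[d], er[d], k600[d],
                                              q2, r2), numeric(1))

  day_ad <- lapply(seq_len(D), function(d)
    new_adapter(c(0.5, 0.5, max(0.2, 0.1 * init_k600))))
  if (pooled) {
    node_ad <- new_adapter(rep(0.05, N))
    skd_ad <- new_adapter(0.3)
    ridge_scale <- 0.1  # sd of the joint ln-shift of nodes and daily K600
  }
  sig_ad <- new_adapter(rep(0.2, if (pooled) 2L else 1L))

  par_names <- c(paste0("GPP.", vapply(tds, function(t) as.character(t$date),
                                       character(1))),
                 paste0("ER.", vapply(tds, function(t) as.character(t$date),
                                      character(1))),
                 paste0("K600.", vapply(tds, function(t) as.character(t$date),
                                        character(1))),
                 if (pooled) paste0("lnK600node.", seq_len(N)),
                 if (pooled) "sigma_K600_daily",
                 "sigma_obs",
                 if (pooled) "sigma_proc")
  out <- matrix(NA_real_, keep, length(par_names),
                dimnames = list(NULL, par_names))

  total <- warm_sweeps + keep * thin
  kept <- 0L
  for (s in seq_len(total)) {
    warm <- s <= warm_sweeps
    for (d in seq_len(D)) {
      cur <- c(gpp[d], er[d], k600[d])
      prop <- cur + adapter_step(day_ad[[d]])
      lp_new <- day_lp(d, prop[1L], prop[2L], prop[3L])
      alpha <- 0
      if (is.finite(lp_new)) {
        ll_new <- day_ll(d, prop[1L], prop[2L], prop[3L], q2, r2)
        delta <- ll_new - Ld[d] + lp_new - day_lp(d, cur[1L], cur[2L],
                                                  cur[3L])
        alpha <- min(1, exp(delta))
        if (runif(1) < alpha) {
          gpp[d] <- prop[1L]; er[d] <- prop[2L]; k600[d] <- prop[3L]
          Ld[d] <- ll_new
        }
      }
      if (warm) day_ad[[d]] <- adapter_update(day_ad[[d]],
                                              c(gpp[d], er[d], k600[d]),
                                              alpha)
    }
    if (pooled) {
      eta2 <- eta + adapter_step(node_ad)
      delta <- node_lp(eta2, skd) - node_lp(eta, skd)
      alpha <- if (is.finite(delta)) min(1, exp(delta)) else 0
      if (runif(1) < alpha) {
        eta <- eta2
        kpred <- exp(approx(grid, eta, xout = lnQ)$y)
      }
      if (warm) node_ad <- adapter_update(node_ad, eta, alpha)

      skd2 <- exp(log(skd) + adapter_step(skd_ad))
      delta <- node_lp(eta, skd2) - node_lp(eta, skd)
      alpha <- if (is.finite(delta)) min(1, exp(delta)) else 0
      if (runif(1) < alpha) skd <- skd2
      if (warm) skd_ad <- adapter_update(skd_ad, log(skd), alpha)

      # ridge move: shift all node ln-values and scale all daily K600 by
      # the same factor (the hierarchy's slow direction); Jacobian D*del
      del <- rnorm(1, 0, ridge_scale)
      eta2 <- eta + del
      k2 <- k600 * exp(del)
      kpred2 <- kpred * exp(del)
      Ld2 <- vapply(seq_len(D), function(d) day_ll(d, gpp[d], er[d],
                                                   k2[d], q2, r2),
                    numeric(1))
      delta <- sum(Ld2) - sum(Ld) +
        sum(dnorm(k2, kpred2, skd, log = TRUE)) -
        sum(dnorm(k600, kpred, skd, log = TRUE)) +
        dnorm(eta2[1L], priors$k600_node_first_meanlog,
              priors$k600_node_first_sdlog, log = TRUE) -
        dnorm(eta[1L], priors$k600_node_first_meanlog,
              priors$k600_node_first_sdlog, log = TRUE) +
        D * del
      alpha <- if (is.finite(delta)) min(1, exp(delta)) else 0
      if (runif(1) < alpha) {
        eta <- eta2; k600 <- k2; kpred <- kpred2; Ld <- Ld2
      }
      if (warm) ridge_scale <- ridge_scale *
          exp(min(0.5, s^-0.6) * (alpha - 0.3))
    }
    {
      cur <- if (pooled) c(log(sobs), log(sproc)) else log(sobs)
      prop <- cur + adapter_step(sig_ad)
      sobs2 <- exp(prop[1L])
      sproc2 <- if (pooled) exp(prop[2L]) else 0
      q2n <- sproc2^2; r2n <- sobs2^2
      Ldn <- vapply(seq_len(D), function(d) day_ll(d, gpp[d], er[d],
                                                   k600[d], q2n, r2n),
                    numeric(1))
      delta <- sum(Ldn) - sum(Ld) + hyper_sigma(sobs2, sproc2) -
        hyper_sigma(sobs, sproc)
      alpha <- if (is.finite(delta)) min(1, exp(delta)) else 0
      if (runif(1) < alpha) {
        sobs <- sobs2; sproc <- sproc2; q2 <- q2n; r2 <- r2n; Ld <- Ldn
      }
      if (warm) sig_ad <- adapter_update(sig_ad,
                                         if (pooled) c(log(sobs),
                                                       log(sproc))
                                         else log(sobs), alpha)
    }
    if (!warm && (s - warm_sweeps) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- c(gpp, er, k600,
                       if (pooled) eta,
                       if (pooled) skd,
                       sobs,
                       if (pooled) sproc)
    }
  }
  out
}

#' MCMC settings
#'
#' `warmup` and `saved` are counted in retained iterations per chain
#' (matching the convention of reporting chain lengths); `thin` is the
#' number of internal blockwise-Metropolis sweeps per retained iteration,
#' so a chain runs `(warmup + saved) * thin` sweeps and keeps `saved`
#' draws.
#'
#' @param chains Number of chains (run sequentially).
#' @param warmup Warmup iterations per chain (discarded; adaptation on).
#' @param saved Saved iterations per chain.
#' @param thin Sweeps per retained iteration.
#' @return A list of MCMC settings.
#' @export
mcmc_spec <- function(chains = 4, warmup = 1000, saved = 500, thin = 10) {
  stopifnot(chains >= 2, warmup >= 1, saved >= 4, thin >= 1)
  list(chains = chains, warmup = warmup, saved = saved, thin = thin)
}

valid_dates <- function(input, validity) {
  if (is.null(validity)) sort(unique(input$date))
  else sort(validity$date[validity$valid])
}

# long-format posterior summary table from a list of chain matrices
summarize_chains <- function(chains) {
  pars <- colnames(chains[[1L]])
  rows <- lapply(pars, function(p) {
    mat <- vapply(chains, function(ch) ch[, p], numeric(nrow(chains[[1L]])))
    x <- as.vector(mat)
    qs <- quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                   type = 7)
    ne <- tryCatch(n_eff(mat), error = function(e) NA_real_)
    rh <- tryCatch(suppressWarnings(rhat(mat)), error = function(e) NA_real_)
    data.frame(name = p, mean = mean(x),
               se_mean = sd(x) / sqrt(max(ne, 1)), sd = sd(x),
               q2.5 = qs[1L], q25 = qs[2L], q50 = qs[3L], q75 = qs[4L],
               q97.5 = qs[5L], Rhat = rh, n_eff = ne,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

assemble_fit <- function(chains_list, tds, grid, model, mcmc, seed,
                         runtime_s, priors, skd_scale, k600_median_prelim) {
  summ <- summarize_chains(chains_list)
  base <- sub("\\..*$", "", summ$name)
  daily <- summ[base %in% c("GPP", "ER", "K600"), ]
  daily <- data.frame(date = as.Date(sub("^[^.]*\\.", "", daily$name)),
                      parameter = sub("\\..*$", "", daily$name),
                      daily[, -1L], stringsAsFactors = FALSE)
  daily <- daily[order(daily$date, daily$parameter), ]
  rownames(daily) <- NULL
  nodes <- NULL
  pool <- NULL
  if (model == "pooled") {
    nd <- summ[base == "lnK600node", ]
    nodes <- data.frame(node = as.integer(sub("^lnK600node\\.", "",
                                              nd$name)),
                        lnQ = grid, nd[, -1L], stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    skd_med <- summ$q50[summ$name == "sigma_K600_daily"]
    pool <- k600_pool(grid, nodes$q50, skd_med)
  }
  overall <- summ[base %in% c("sigma_K600_daily", "sigma_obs",
                              "sigma_proc"), ]
  names(overall)[1L] <- "parameter"
  rownames(overall) <- NULL
  structure(list(
    daily = daily, nodes = nodes, overall = overall, pool = pool,
    dates = as.Date(vapply(tds, function(t) as.character(t$date),
                           character(1))),
    lnQ = vapply(tds, `[[`, numeric(1), "lnQ"),
    model = model,
    draws = chains_list,
    mcmc = c(mcmc, list(seed = seed, runtime_s = runtime_s)),
    config = list(priors = priors, skd_scale = skd_scale,
                  k600_median_prelim = k600_median_prelim),
    rerun = FALSE), class = "metab_fit")
}

#' Preliminary unpooled metabolism fit
#'
#' Fits the observation-error-only model with independent daily K600 priors
#' (no process error, no pooling). Its purpose is to supply the median daily
#' K600 that scales the pooled model's half-normal hyperprior on the daily
#' K600 deviation sd (2% of that median). If the preliminary chains do not
#' converge (any daily K600 split R-hat > 1.2) the fit is flagged and the
#' pooled model falls back to a configurable default scale.
#'
#' @param input A `metab_input` table.
#' @param validity Optional validity table; only valid days are fitted.
#' @param priors A [prior_spec].
#' @param mcmc An [mcmc_spec] list.
#' @param seed Integer RNG seed.
#' @return A `metab_fit` with elements `median_K600` (median over days of
#'   the daily K600 posterior medians) and `converged`.
#' @export
fit_preliminary_nopool <- function(input, validity = NULL,
                                   priors = prior_spec(),
                                   mcmc = mcmc_spec(), seed = 1) {
  dates <- valid_dates(input, validity)
  if (length(dates) == 0L) stop("no valid days to fit")
  tds <- day_tensors(input, dates)
  t0 <- proc.time()[["elapsed"]]
  chains_list <- lapply(seq_len(mcmc$chains), function(ch)
    run_metab_chain(tds, "nopool", priors, grid = NULL, skd_scale = NA,
                    warm_sweeps = mcmc$warmup * mcmc$thin,
                    keep = mcmc$saved, thin = mcmc$thin,
                    chain_seed = seed * 1000L + ch, init_k600 = 5))
  fit <- assemble_fit(chains_list, tds, NULL, "nopool", mcmc, seed,
                      proc.time()[["elapsed"]] - t0, priors, NA, NA)
  kd <- fit$daily[fit$daily$parameter == "K600", ]
  fit$median_K600 <- median(kd$q50)
  fit$converged <- all(is.finite(kd$Rhat)) && max(kd$Rhat) <= 1.2
  if (!fit$converged)
    message("preliminary unpooled fit did not converge; ",
            "downstream hyperprior will use the fallback scale")
  fit
}

#' Fit the hierarchical metabolism model
#'
#' Samples the posterior of the state-space diel oxygen model
#' ([state_space_logdensity]) for all valid days jointly: daily GPP, ER and
#' K600, the K600~Q node values (built by [build_nodes] at 0.2-ln-unit
#' spacing over the observed daily discharge range), the daily-K600
#' deviation sd, and the observation and process error SDs. Daily K600
#' values are partially pooled toward the piecewise-linear node relationship.
#'
#' The half-normal scale of the daily-K600 deviation sd is 2% of the median
#' preliminary K600 ([fit_preliminary_nopool]); pass `k600_median_prelim` to
#' reuse a preliminary run, or set `priors$sigma_kd_scale` directly. If
#' neither is given a preliminary run is performed internally.
#'
#' @param input A `metab_input` table (from [merge_and_interpolate] /
#'   [prepare_model_input]).
#' @param validity Optional validity table; only valid days are fitted.
#' @param priors A [prior_spec].
#' @param mcmc An [mcmc_spec] list.
#' @param seed Integer RNG seed; fixed seed and inputs give identical
#'   results.
#' @param k600_median_prelim Median daily K600 (d-1) from a preliminary
#'   unpooled run, or `NA` to force the fallback scale.
#' @return An object of class `metab_fit`: posterior summaries (`daily`,
#'   `nodes`, `overall`; mean, se_mean, sd, percentiles 2.5/25/50/75/97.5,
#'   split R-hat, n_eff), the fitted [k600_pool] (`pool`, node and sd
#'   medians), raw draws per chain (`draws`), and run metadata (`mcmc`).
#' @export
fit_metabolism <- function(input, validity = NULL, priors = prior_spec(),
                           mcmc = mcmc_spec(), seed = 1,
                           k600_median_prelim = NULL) {
  dates <- valid_dates(input, validity)
  if (length(dates) == 0L) stop("no valid days to fit")
  tds <- day_tensors(input, dates)
  lnQ <- vapply(tds, `[[`, numeric(1), "lnQ")
  if (any(!is.finite(lnQ)))
    stop("nonpositive daily mean discharge on a fitted day; ",
         "apply filter_positive_flow first")
  grid <- build_nodes(lnQ)

  if (is.null(priors$sigma_kd_scale)) {
    if (is.null(k600_median_prelim)) {
      message("running preliminary unpooled fit to scale the K600 hyperprior")
      prelim <- fit_preliminary_nopool(input, validity, priors, mcmc,
                                       seed = seed + 101L)
      k600_median_prelim <- if (prelim$converged) prelim$median_K600 else
        NA_real_
    }
    if (is.finite(k600_median_prelim)) {
      skd_scale <- 0.02 * k600_median_prelim
    } else {
      warning("no usable preliminary K600 median; using fallback scale ",
              priors$sigma_kd_fallback, " d-1")
      skd_scale <- priors$sigma_kd_fallback
    }
  } else {
    skd_scale <- priors$sigma_kd_scale
  }
  init_k600 <- if (!is.null(k600_median_prelim) &&
                   is.finite(k600_median_prelim)) k600_median_prelim else 5

  t0 <- proc.time()[["elapsed"]]
  chains_list <- lapply(seq_len(mcmc$chains), function(ch)
    run_metab_chain(tds, "pooled", priors, grid, skd_scale,
                    warm_sweeps = mcmc$warmup * mcmc$thin,
                    keep = mcmc$saved, thin = mcmc$thin,
                    chain_seed = seed * 1000L + ch,
                    init_k600 = init_k600))
  assemble_fit(chains_list, tds, grid, "pooled", mcmc, seed,
               proc.time()[["elapsed"]] - t0, priors, skd_scale,
               k600_median_prelim)
}

#' Re-run a fit that failed to converge
#'
#' Convergence is judged on the two key overall parameters: the daily-K600
#' deviation sd and the process error sd. If either split R-hat exceeds 1.2
#' the model is refitted once with 2000 warmup and 2000 saved iterations per
#' chain; the refit is returned regardless of its own convergence (a still
#' unconverged refit earns Low confidence downstream). Converged fits are
#' returned unchanged.
#'
#' @param fit A pooled `metab_fit`.
#' @param input,validity The inputs the fit was produced from.
#' @return A `metab_fit`; `$rerun` is `TRUE` if a refit happened.
#' @export
rerun_if_unconverged <- function(fit, input, validity = NULL) {
  stopifnot(inherits(fit, "metab_fit"), fit$model == "pooled")
  if (key_rhat(fit) <= 1.2) return(fit)
  mc <- mcmc_spec(chains = fit$mcmc$chains, warmup = 2000, saved = 2000,
                  thin = fit$mcmc$thin)
  pr <- fit$config$priors
  pr$sigma_kd_scale <- fit$config$skd_scale
  refit <- fit_metabolism(input, validity, priors = pr, mcmc = mc,
                          seed = fit$mcmc$seed,
                          k600_median_prelim = fit$config$k600_median_prelim)
  refit$rerun <- TRUE
  refit
}

# max split R-hat of the two key overall SDs
key_rhat <- function(fit) {
  keys <- c("sigma_K600_daily", "sigma_proc")
  r <- fit$overall$Rhat[fit$overall$parameter %in% keys]
  if (length(r) == 0L || any(!is.finite(r))) return(Inf)
  max(r)
}

#' @export
print.metab_fit <- function(x, ...) {
  cat(sprintf("<metab_fit> %s model: %d days, %s chains x %d saved (thin %d), %.1f s\n",
              x$model, length(x$dates), x$mcmc$chains, x$mcmc$saved,
              x$mcmc$thin, x$mcmc$runtime_s))
  gpp <- x$daily[x$daily$parameter == "GPP", ]
  er <- x$daily[x$daily$parameter == "ER", ]
  k <- x$daily[x$daily$parameter == "K600", ]
  cat(sprintf("  median GPP %.2f, ER %.2f g O2 m-2 d-1; K600 %.2f d-1\n",
              median(gpp$q50), median(er$q50), median(k$q50)))
  if (!is.null(x$overall) && nrow(x$overall))
    cat(sprintf("  max key Rhat %.3f\n",
                suppressWarnings(tryCatch(key_rhat(x),
                                          error = function(e) NA))))
  invisible(x)
}
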