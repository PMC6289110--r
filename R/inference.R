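#' Prior specification for the metabolism model
#'
#' Defaults follow literature-based priors for daily metabolism: GPP ~
#' normal(3.1, 6.0) g O2 m-2 d-1, ER ~ normal(-7.1, 7.1) g O2 m-2 d-1.
#' The K600~Q node values get a random-walk prior on the log scale: each
#' node's log(K600_n) is normal with sd 0.1 around the node to its left; the
#' first node (not defined by that rule) gets a weakly informative lognormal
#' centered on ln(5 d-1) with sd 1. Daily K600_d deviations from the pooled
#' prediction are normal on the natural scale with sd `sigma_K600_daily`,
#' itself half-normal with scale 2% of the median preliminary K600 (set at
#' fit time unless `sigma_kd_scale` is supplied). Error SDs get half-normal
#' priors (scales in mg L-1; the process scale is per timestep).
#'
#' @param gpp_mean,gpp_sd GPP prior, g O2 m-2 d-1.
#' @param er_mean,er_sd ER prior, g O2 m-2 d-1.
#' @param k600_node_first_meanlog,k600_node_first_sdlog First-node lognormal
#'   prior on K600 (d-1).
#' @param k600_node_walk_sd Random-walk sd between adjacent node log-values.
#' @param sigma_kd_scale Half-normal scale for the daily K600 deviation sd;
#'   `NULL` means derive it as `0.02 *` the preliminary-run median K600.
#' @param sigma_kd_fallback Scale used if the preliminary run did not
#'   converge, d-1.
#' @param sigma_obs_scale,sigma_proc_scale Half-normal scales for the
#'   observation and process error SDs, mg L-1.
#' @param k600_nopool_meanlog,k600_nopool_sdlog Independent daily lognormal
#'   K600 prior used by the unpooled preliminary model.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(gpp_mean = 3.1, gpp_sd = 6.0,
                       er_mean = -7.1, er_sd = 7.1,
                       k600_node_first_meanlog = log(5),
                       k600_node_first_sdlog = 1,
                       k600_node_walk_sd = 0.1,
                       sigma_kd_scale = NULL,
                       sigma_kd_fallback = 0.1,
                       sigma_obs_scale = 0.1,
                       sigma_proc_scale = 0.2,
                       k600_nopool_meanlog = log(5),
                       k600_nopool_sdlog = 1) {
  p <- as.list(environment())
  scales <- c(p$gpp_sd, p$er_sd, p$k600_node_first_sdlog, p$k600_node_walk_sd,
              p$sigma_kd_fallback, p$sigma_obs_scale, p$sigma_proc_scale,
              p$k600_nopool_sdlog, p$sigma_kd_scale)
  if (any(scales <= 0)) stop("all prior scale parameters must be > 0")
  structure(p, class = "prior_spec")
}

#' K600~discharge pool
#'
#' The piecewise-linear relationship between log K600 and log daily mean
#' discharge: node positions at 0.2-natural-log spacing spanning the
#' observed ln(Q) range, node log-K600 values, and the sd of daily K600
#' deviations around the pooled prediction (natural scale, d-1).
#'
#' @param node_lnQ Node positions, ln(m3 s-1); spacing 0.2.
#' @param node_lnK600 Node values, ln(d-1).
#' @param sigma_K600_daily Daily deviation sd, d-1.
#' @return An object of class `k600_pool`.
#' @export
k600_pool <- function(node_lnQ, node_lnK600, sigma_K600_daily = NA_real_) {
  if (length(node_lnQ) < 2L) stop("need at least 2 nodes")
  if (length(node_lnQ) != length(node_lnK600))
    stop("node_lnQ and node_lnK600 lengths differ")
  if (any(abs(diff(node_lnQ) - 0.2) > 1e-8))
    stop("node spacing must be exactly 0.2 natural log units")
  structure(list(node_lnQ = node_lnQ, node_lnK600 = node_lnK600,
                 sigma_K600_daily = sigma_K600_daily),
            class = "k600_pool")
}

#' Build the K600~Q node grid
#'
#' Places linearly connected nodes at fixed intervals of 0.2 natural log
#' units along the range of observed daily mean discharge: the grid is
#' anchored at the minimum observed ln(Q) and extended in 0.2 steps until it
#' covers the maximum (at least 2 nodes, so a constant-discharge record
#' still gets a bracketing grid).
#'
#' @param daily_lnQ Daily mean ln(discharge), ln(m3 s-1); at least 1 finite
#'   value.
#' @return Numeric vector of node positions (first node <= min, last >=
#'   max).
#' @export
build_nodes <- function(daily_lnQ) {
  daily_lnQ <- daily_lnQ[is.finite(daily_lnQ)]
  if (length(daily_lnQ) == 0L) stop("need at least one finite daily lnQ")
  lo <- min(daily_lnQ)
  span <- max(daily_lnQ) - lo
  n_int <- max(1L, as.integer(ceiling(span / 0.2 - 1e-9)))
  lo + 0.2 * (0:n_int)
}

#' Pooled K600 prediction at a daily discharge
#'
#' Linear interpolation of the node log-K600 values at a day's ln(Q)
#' (queries are clamped to the node span, which [build_nodes] guarantees
#' covers the observed range).
#'
#' @param lnQ_d Daily mean ln(discharge).
#' @param pool A [k600_pool].
#' @return Predicted ln(K600), same length as `lnQ_d`.
#' @export
piecewise_predict <- function(lnQ_d, pool) {
  stopifnot(inherits(pool, "k600_pool"))
  x <- pmin(pmax(lnQ_d, min(pool$node_lnQ)), max(pool$node_lnQ))
  approx(pool$node_lnQ, pool$node_lnK600, xout = x)$y
}

# half-normal(0, scale) log density
lp_halfnorm <- function(x, scale) {
  ifelse(x < 0, -Inf, dnorm(x, 0, scale, log = TRUE) + log(2))
}

# full log prior of the pooled model (daily params + nodes + error SDs);
# the K600_d >= 0 truncation's normalization constant is omitted
log_prior_all <- function(params, pool, errors, priors, lnQ) {
  kpred <- exp(piecewise_predict(lnQ, pool))
  skd <- pool$sigma_K600_daily
  if (!is.finite(skd) || skd <= 0) return(-Inf)
  if (any(params$K600 < 0)) return(-Inf)
  lp <- sum(dnorm(params$GPP, priors$gpp_mean, priors$gpp_sd, log = TRUE)) +
    sum(dnorm(params$ER, priors$er_mean, priors$er_sd, log = TRUE)) +
    sum(dnorm(params$K600, kpred, skd, log = TRUE))
  eta <- pool$node_lnK600
  lp <- lp + dnorm(eta[1L], priors$k600_node_first_meanlog,
                   priors$k600_node_first_sdlog, log = TRUE)
  if (length(eta) > 1L)
    lp <- lp + sum(dnorm(diff(eta), 0, priors$k600_node_walk_sd, log = TRUE))
  skd_scale <- if (is.null(priors$sigma_kd_scale)) priors$sigma_kd_fallback
               else priors$sigma_kd_scale
  lp + lp_halfnorm(skd, skd_scale) +
    lp_halfnorm(errors$sigma_obs, priors$sigma_obs_scale) +
    lp_halfnorm(errors$sigma_proc, priors$sigma_proc_scale)
}

#' Split-chain potential scale reduction factor
#'
#' The split R-hat convergence statistic: each chain is split in half and
#' the usual between/within variance ratio is computed over the resulting
#' half-chains, so within-chain trends inflate the statistic. Chains with
#' zero total variance return 1 by convention, with a degenerate-chain
#' warning.
#'
#' @param draws Matrix of posterior draws, iterations x chains (>= 2 chains,
#'   >= 4 iterations).
#' @return Scalar R-hat.
#' @export
rhat <- function(draws) {
  s <- split_chains(draws)
  n <- nrow(s); m <- ncol(s)
  W <- mean(apply(s, 2L, var))
  B <- n * var(colMeans(s))
  if (!is.finite(W) || W == 0) {
    if (is.finite(B) && B > 0) return(Inf)
    warning("degenerate chains (zero variance); returning Rhat = 1")
    return(1)
  }
  varplus <- (n - 1) / n * W + B / n
  sqrt(varplus / W)
}

#' Effective number of MCMC samples
#'
#' Autocorrelation-based effective sample size over split chains: lag
#' autocovariances are averaged across chains, converted to correlations
#' against the pooled-variance estimate, and summed with Geyer's initial
#' monotone positive-pair rule. Capped at the total number of draws.
#'
#' @inheritParams rhat
#' @return Scalar effective sample size.
#' @export
n_eff <- function(draws) {
  s <- split_chains(draws)
  n <- nrow(s); m <- ncol(s)
  W <- mean(apply(s, 2L, var))
  B <- n * var(colMeans(s))
  if (!is.finite(W) || W == 0) return(m * n)
  varplus <- (n - 1) / n * W + B / n
  max_lag <- n - 2L
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(s[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    a
  }, numeric(max_lag + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1L]) / varplus
  # Geyer initial monotone positive sequence over lag pairs
  tau <- 1
  npair <- floor(length(rho) / 2)
  last <- Inf
  if (npair >= 1) {
    for (p in seq_len(npair)) {
      pair <- rho[2 * p - 1L] + rho[2 * p]
      if (pair < 0) break
      pair <- min(pair, last)
      last <- pair
      tau <- tau + 2 * pair
    }
  }
  min(m * n, m * n / tau)
}

split_chains <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("need at least 2 chains")
  if (nrow(draws) < 4L) stop("need at least 4 draws per chain")
  n2 <- floor(nrow(draws) / 2)
  cbind(draws[seq_len(n2), , drop = FALSE],
        draws[nrow(draws) - n2 + seq_len(n2), , drop = FALSE])
}
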