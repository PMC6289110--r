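---
title: "Estimating stream metabolism from diel dissolved oxygen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stream metabolism from diel dissolved oxygen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Dissolved oxygen in a stream reach integrates three processes that act in
different directions and with different diel timing: photosynthetic
production (GPP), aerobic respiration (ER), and physical air-water gas
exchange. oxbow fits the daily mass balance

$$\frac{dO_{i,d}}{dt} \;=\; \frac{GPP_d}{\bar z_{i,d}}
\cdot \frac{PPFD_{i,d}}{\overline{PPFD}_d}
\;+\; \frac{ER_d}{\bar z_{i,d}}
\;+\; KO2_{i,d}\,\bigl(Osat_{i,d} - O_{i,d}\bigr)$$

where $O_{i,d}$ is the modeled oxygen concentration (mg L$^{-1}$) at
timestep $i$ of day $d$; $GPP_d > 0$ and $ER_d < 0$ are daily
reach-averaged rates (g O$_2$ m$^{-2}$ d$^{-1}$); $\bar z$ is mean upstream
reach depth (m); $PPFD$ is photosynthetic photon flux density; $Osat$ is
the temperature- and pressure-dependent saturation concentration; and
$KO2 = K600\,(Sc_{O2}/600)^{-1/2}$ converts the daily gas exchange
coefficient $K600_d$ (d$^{-1}$, normalized to Schmidt number 600) to its
oxygen- and temperature-specific value. Because the GPP term uses only the
ratio of instantaneous to daily-mean light, the PPFD units cancel; the
package carries PPFD in µmol m$^{-2}$ s$^{-1}$ throughout.

The balance is integrated with the trapezoid rule. The gas-exchange term
makes the update implicit in $O_{i+1}$, but only linearly, so each step is
solved in closed form (no iterative solver):

$$O_{i+1}\Bigl(1 + \tfrac{\Delta t\,k_{i+1}}{2}\Bigr) =
O_i\Bigl(1 - \tfrac{\Delta t\,k_i}{2}\Bigr) +
\tfrac{\Delta t}{2}\,(c_i + c_{i+1})$$

with $k_i = KO2_i$ and $c_i$ collecting the source terms.

### State-space error structure

The model is a state-space time series model: latent oxygen states follow
the deterministic trapezoid update plus Gaussian *process error*
($\sigma_{proc}$, per timestep), and observations equal the states plus
Gaussian *observation error* ($\sigma_{obs}$). Fitting to both the
concentrations and the stepwise concentration changes yields more accurate
rates and honest uncertainty compared to either error source alone. Gas
exchange always acts on the modeled state, never directly on the
observations.

Given the daily parameters the update is linear in oxygen, so the model is
linear-Gaussian and the latent states can be marginalized *analytically*
with a scalar Kalman filter. `state_space_logdensity()` exposes both
forms: the marginal likelihood of the observations (used for inference)
and the joint density of explicit states and observations. Marginalization
changes nothing about the posterior over the parameters; it only removes
~100 latent dimensions per day from the sampling problem.

Two conventions complete the likelihood. Each day's initial state is the
day's first oxygen observation (the convention of the model-variant family
this implements; the source releases do not restate it, so it is flagged
here). Consequently the observation term at that first timestep is
omitted — the first observation defines the state rather than measuring
it. Missing oxygen values inside a retained day (gaps of at most 3 h) stay
on the uniform time grid as `NA` observations; the Kalman filter simply
skips those update steps, which is exactly the likelihood of the observed
subset.

## Priors and hierarchical pooling

* $GPP_d \sim \mathcal N(3.1,\,6.0^2)$ and
  $ER_d \sim \mathcal N(-7.1,\,7.1^2)$ g O$_2$ m$^{-2}$ d$^{-1}$
  (literature-range priors).
* $K600$ is partially pooled: a piecewise-linear relationship between
  $\ln K600$ and $\ln Q$ (daily mean discharge) is built from nodes at
  fixed 0.2-natural-log intervals spanning the observed $\ln Q$ range
  (`build_nodes()`; the grid is anchored at the observed minimum, at least
  2 nodes). Each node's $\ln K600_n$ prior is normal with sd 0.1 around
  the node to its left; the first node, which that rule leaves undefined,
  gets a weakly informative lognormal centered on $\ln(5\ \mathrm{d}^{-1})$
  with sd 1 (configurable).
* Daily values deviate from the pooled prediction as
  $K600_d \sim \mathcal N(\exp(\text{pred}_d),\,\sigma_{K600}^2)$ on the
  *natural* scale (d$^{-1}$), truncated at zero. The source material is
  ambiguous between the log and natural scales here; the natural scale
  matches the scale on which the hyperprior is expressed. The truncation's
  normalization constant is omitted — negligible whenever the prediction
  exceeds a few multiples of $\sigma_{K600}$, as in all realistic fits.
* $\sigma_{K600} \sim \text{half-}\mathcal N(0, s^2)$ with $s$ equal to 2%
  of the median daily K600 from a **preliminary unpooled fit**
  (`fit_preliminary_nopool()`: observation error only, independent
  lognormal($\ln 5$, 1) daily K600 priors). If the preliminary fit does
  not converge, a configurable fallback scale (default 0.1 d$^{-1}$) is
  used and a warning is raised.
* $\sigma_{obs}$ and $\sigma_{proc}$ priors are not stated in the source
  material; half-normal(0, 0.1) and half-normal(0, 0.2) mg L$^{-1}$
  defaults are used (the process scale is per timestep at the chunk's
  resolution, not scaled by $\sqrt{\Delta t}$), both configurable in
  `prior_spec()`.

## Sampling and diagnostics

The posterior is sampled with blockwise adaptive Metropolis: one 3-d block
per day ($GPP_d, ER_d, K600_d$) with a Haario-style adapted full
covariance, a block for the node values, scalar blocks for
$\ln\sigma_{K600}$ and the log error SDs, and a dedicated "ridge" move
that shifts all node values and rescales all daily K600 by a common
factor — the slow direction of the hierarchy. Adaptation (covariance and
Robbins-Monro step scaling toward 0.3 acceptance) runs during warmup only,
so the sampling phase is a fixed kernel. The spec of the posterior, not
the sampler, is the contract; any sampler reproducing it is equivalent.

`mcmc_spec()` counts `warmup` and `saved` in retained iterations per chain
(the convention in which run lengths like 4 chains × 1000 warmup + 500
saved are reported), with `thin` internal sweeps per retained iteration
(default 10) because a Metropolis sweep moves less far than a gradient
step. Chains run sequentially and are seed-reproducible.

Convergence is summarized per parameter with the split R-hat statistic and
an autocorrelation-based effective sample size (Geyer initial monotone
positive-pair rule), implemented in `rhat()` / `n_eff()`. Zero-variance
chains report R-hat 1 with a degenerate-chain warning. A model "fails to
converge" when the split R-hat of either key SD — $\sigma_{K600}$ or
$\sigma_{proc}$ — exceeds 1.2; `rerun_if_unconverged()` then refits once
at 2000 warmup / 2000 saved and returns that refit regardless of its own
convergence (a still-unconverged refit earns Low confidence downstream).

## From raw series to model inputs

Metabolism days run 04:00–03:59 in *mean solar time* (a fixed 4 min/degree
longitude shift of UTC), which assigns observations to days; *apparent
solar time* (adding Spencer's equation of time) drives the clear-sky light
model. Oxygen saturation uses the Garcia–Gordon (Benson–Krause
coefficient) solubility fit with a barometric correction
$(P - p_{H_2O})/(P_0 - p_{H_2O})$ (Magnus-type vapor pressure).
Elevation-only pressure uses the international standard atmosphere.
Shortwave radiation converts to PPFD with a fixed 2.114 µmol J$^{-1}$
multiplier; `calc_light_merged()` downscales the coarse (hourly)
observation-based PPFD onto the fine oxygen timestamps by linearly
interpolating the observed/modeled ratio, with ratio anchors at the coarse
timestamps (endpoint anchoring; the alternative midpoint convention is not
used) and zero output wherever modeled light is zero. Depth and velocity
come from at-a-station hydraulic-geometry power laws $c\,Q^f$ and
$k\,Q^m$ with $Q$ in m$^3$ s$^{-1}$ (raw gauge discharge in ft$^3$
s$^{-1}$ is converted by 0.0283168).

Input assembly (`prepare_model_input()`) enforces the day-quality rules:

* non-oxygen variables are linearly interpolated onto the oxygen
  timestamps, filling gaps of at most 3 h (measured between consecutive
  available timestamps of each variable; strictly longer excludes);
* a day whose window overlaps a longer gap in *any* variable is excluded
  whole (`gap>3h`);
* days whose windows extend beyond the record span (chunk edges) are
  excluded as `incomplete_window` — a partial day would bias daily rates;
* days containing any nonpositive discharge are excluded
  (`nonpositive_flow`), avoiding intermittent or tidal conditions;
* records with changing logging resolution are split into
  uniform-resolution chunks (`split_by_resolution()`), one model per
  chunk; a new resolution must persist for at least 12 intervals, so
  isolated missing timestamps do not split a record.

Each excluded date carries exactly one primary reason, logged to the
per-model daily-messages table. Storm days are *not* filtered: storm peaks
do not always corrupt estimates, so they are left to downstream users to
screen.

## Diagnostics and confidence

`assess_model()` computes per-model metrics from the daily posterior
medians (the release-style central estimate; means would be the obvious
alternative, and medians are chosen to match the use of the 50th
percentile as the central estimate): the P90–P10 range of daily K600, the
percentages of GPP medians below −0.5 and ER medians above +0.5
(biologically unrealistic signs; values within ±0.5 are treated as
indistinguishable from zero), and the key-SD max R-hat.
`assess_confidence()` applies the rule set: Low if R-hat > 1.2 or K600
range > 50 d$^{-1}$ or either percentage > 50; High only if R-hat < 1.2,
range < 15, and both percentages < 25; otherwise Medium (a value exactly
at a threshold is Medium; thresholds are strict inequalities as printed).
Sites with several models get the minimum label plus the comma-joined
list.

The estimate's spatial footprint is the daily 80% turnover distance
$L_d = -\ln(1-0.8)\,v/KO2_d$ (v in m d$^{-1}$). Distances to upstream
structures (canals, dams, permitted discharges) are classed by the highest
percentile of the $L_d$ distribution (P0/P50/P80/P95) that the distance
strictly exceeds, ties falling to the lower class and absent structures to
P95. Percentiles use linear interpolation between order statistics
(`quantile` type 7).

## The synthetic generator

`generate_site()` emulates the statistical shape of the raw inputs with
known truth: lognormal AR(1) daily discharge smoothly interpolated within
days; water temperature as a diel sinusoid plus AR(1) noise; hourly
pressure around the standard atmosphere; hourly shortwave as clear-sky
light attenuated by a beta-distributed daily cloud factor; true daily GPP
tied to realized daily light (so clouds induce realistic covariation;
configurable off); true K600 following a two-segment piecewise function of
$\ln Q$ with optional daily deviations; and oxygen simulated from exactly
the trapezoid state-space process the model assumes, using forcings
derived with the package's own functions — so with zero noise the pipeline
reproduces the latent path to machine precision. The default site is a
temperate mid-order stream: depth ≈ 0.5 m, median K600 ≈ 10 d$^{-1}$, GPP
≈ 2–8 and ER ≈ −4 to −12 g O$_2$ m$^{-2}$ d$^{-1}$, observation error 0.05
mg L$^{-1}$ and process error 0.02 mg L$^{-1}$ per 15-min step.

What it does **not** emulate: sensor drift and fouling, groundwater oxygen
fluxes, storm hysteresis in the depth–discharge relation, tidal reversals
(beyond simple injected zero-flow readings), or model misspecification in
general. Passing recovery tests therefore demonstrates that the inference
machinery inverts the assumed generative process — not that the model is
correct for any particular real river.

## Numerical choices and problem sizes

* The implicit trapezoid step is solved analytically; no ODE solver is
  involved in the likelihood.
* Negative modeled oxygen is mathematically permitted (Gaussian state
  space) and triggers a warning in `simulate_day()`.
* Fits in the tests and the acceptance script use 14 days of 15-min data
  (or less) with scaled-down chain lengths (e.g. 2–4 chains, a few
  hundred retained iterations, thin 5–8), chosen so a full two-stage fit
  completes in tens of seconds while leaving clear margin on the recovery
  tolerances; production-scale multi-year records would simply use the
  default 4 × (1000 + 500) × 10 settings and more wall time.
* Seed handling: each chain derives its RNG seed from the fit seed, so
  identical seeds and inputs give byte-identical summaries.

## Known limitations

* Mean reach depth scales GPP and ER directly; hydraulic-geometry depth
  coefficients carry unquantified uncertainty that propagates into the
  rates.
* The observation-initialized daily state makes day 1 of each day's path
  inherit that observation's noise; with very noisy sensors a diffuse
  initial-state prior would be preferable.
* The per-step (rather than per-$\sqrt{\Delta t}$) process-error
  convention means $\sigma_{proc}$ is not comparable across resolutions.
* No despiking or drift correction is applied to oxygen; miscalibrated
  sensors typically surface as positive ER in the confidence assessment
  rather than being repaired.
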