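#' Daily reach length (80% oxygen turnover distance)
#'
#' The footprint of a single-station metabolism estimate: the distance over
#' which a fraction `renewal_fraction` of the dissolved oxygen pool is
#' renewed by gas exchange, `L = -ln(1 - fraction) * v / KO2`.
#'
#' @param velocity Daily mean velocity, m d-1 (> 0).
#' @param KO2 Oxygen-specific gas exchange rate coefficient, d-1 (> 0).
#' @param renewal_fraction Gas renewal fraction defining the reach (default
#'   0.8).
#' @return Reach length, m.
#' @export
reach_length <- function(velocity, KO2, renewal_fraction = 0.8) {
  if (any(velocity <= 0, na.rm = TRUE)) stop("velocity must be > 0")
  if (any(KO2 <= 0, na.rm = TRUE)) stop("KO2 must be > 0")
  -log(1 - renewal_fraction) * velocity / KO2
}

#' Model confidence rating
#'
#' Classifies a fitted model as Low, Medium, or High confidence from four
#' metrics: the max split R-hat of the two key SD parameters (daily-K600
#' deviation sd and process error sd), the P90 - P10 range of daily K600
#' medians (d-1), and the percentages of daily GPP medians below -0.5 and ER
#' medians above 0.5 (biologically unrealistic signs). Low if any of:
#' R-hat > 1.2, K600 range > 50, %GPP < -0.5 above 50, %ER > 0.5 above 50.
#' High only if all of: R-hat < 1.2, K600 range < 15, both percentages
#' < 25. Otherwise Medium (a value exactly at a threshold is Medium).
#'
#' @param rhat_max_key Max R-hat over the two key SD parameters.
#' @param k600_range P90 - P10 of daily K600 medians, d-1.
#' @param pct_gpp_neg Percent of daily GPP medians < -0.5.
#' @param pct_er_pos Percent of daily ER medians > 0.5.
#' @return `"Low"`, `"Medium"`, or `"High"`.
#' @export
assess_confidence <- function(rhat_max_key, k600_range, pct_gpp_neg,
                              pct_er_pos) {
  vals <- c(rhat_max_key, k600_range, pct_gpp_neg, pct_er_pos)
  if (length(vals) != 4L || any(is.na(vals)))
    stop("all four assessment metrics must be present")
  if (rhat_max_key > 1.2 || k600_range > 50 || pct_gpp_neg > 50 ||
        pct_er_pos > 50) return("Low")
  if (rhat_max_key < 1.2 && k600_range < 15 && pct_gpp_neg < 25 &&
        pct_er_pos < 25) return("High")
  "Medium"
}

#' Site-level confidence summary
#'
#' Sites can have several models (one per input resolution chunk). The site
#' summary is (a) the minimum confidence over its models (Low < Medium <
#' High) and (b) the comma-joined list of model confidences in model order.
#'
#' @param labels Character vector of `"Low"`/`"Medium"`/`"High"` labels
#'   (>= 1).
#' @return List with `minimum` and `list` (comma-separated string).
#' @export
site_confidence <- function(labels) {
  lv <- c("Low", "Medium", "High")
  if (length(labels) == 0L || !all(labels %in% lv))
    stop("labels must be Low/Medium/High, length >= 1")
  list(minimum = lv[min(match(labels, lv))],
       list = paste(labels, collapse = ","))
}

#' Structural interference class
#'
#' Compares the distance to the nearest upstream structure of each type
#' (canal/ditch, dam, permitted discharge point) with the distribution of
#' daily reach lengths. The class names the highest percentile of daily
#' reach lengths (0th, 50th, 80th, 95th) that the distance strictly
#' exceeds: `"P95"` means the structure is beyond the 95th percentile
#' (interferes on < 5% of days); `"P0"` means it is within the 0th-50th
#' percentile band (possibly inside the reach on some days). Ties at a
#' threshold fall to the lower (more conservative) class. Absent structures
#' are classed `"P95"` (none known within the reach-length distribution).
#'
#' @param distances Named numeric vector or list of structure distances (m);
#'   `NA` or missing entries mean no known structure of that type.
#' @param daily_reach_lengths Daily reach lengths `L_d`, m (>= 1 value).
#' @return Named character vector of classes (`"P0"`, `"P50"`, `"P80"`,
#'   `"P95"`) for each structure type.
#' @export
structure_interference <- function(distances, daily_reach_lengths) {
  L <- daily_reach_lengths[is.finite(daily_reach_lengths)]
  if (length(L) == 0L) stop("need at least one daily reach length")
  thresh <- quantile(L, c(0, 0.5, 0.8, 0.95), names = FALSE, type = 7)
  classes <- c("P0", "P50", "P80", "P95")
  distances <- unlist(distances)
  vapply(seq_along(distances), function(i) {
    d <- distances[[i]]
    if (is.na(d)) return("P95")
    above <- which(d > thresh)
    if (length(above) == 0L) "P0" else classes[max(above)]
  }, character(1), USE.NAMES = FALSE) -> out
  names(out) <- names(distances)
  out
}

#' Assess a fitted model
#'
#' Computes the per-model diagnostic record: max key R-hat, the P90 - P10
#' range of daily K600 posterior medians, the percentages of unrealistic
#' daily GPP and ER medians, the median daily K600, run time, and the
#' resulting confidence label ([assess_confidence]).
#'
#' @param fit A pooled `metab_fit`.
#' @param model_id Identifier for the model (site/chunk).
#' @return One-row data.frame (an assessment record).
#' @export
assess_model <- function(fit, model_id = "model") {
  stopifnot(inherits(fit, "metab_fit"))
  gpp <- fit$daily$q50[fit$daily$parameter == "GPP"]
  er <- fit$daily$q50[fit$daily$parameter == "ER"]
  k <- fit$daily$q50[fit$daily$parameter == "K600"]
  rh <- key_rhat(fit)
  kq <- quantile(k, c(0.1, 0.9), names = FALSE, type = 7)
  rec <- data.frame(
    model_id = model_id,
    rhat_max_key = rh,
    k600_range = kq[2L] - kq[1L],
    pct_gpp_neg = 100 * mean(gpp < -0.5),
    pct_er_pos = 100 * mean(er > 0.5),
    median_K600 = median(k),
    run_hours = fit$mcmc$runtime_s / 3600,
    stringsAsFactors = FALSE)
  rec$confidence <- assess_confidence(rec$rhat_max_key, rec$k600_range,
                                      rec$pct_gpp_neg, rec$pct_er_pos)
  rec
}

#' Daily predictor table
#'
#' The predictor set reported alongside daily metabolism estimates: daily
#' means of oxygen, oxygen saturation, water temperature, shortwave
#' radiation, depth, discharge and velocity; the daily amplitude of percent
#' oxygen saturation; daylight hours (PPFD > 0); and the 80% oxygen
#' turnover distance (from daily K600 medians, the daily mean temperature
#' and velocity).
#'
#' @param input A `metab_input` table.
#' @param fit A pooled `metab_fit` covering (a subset of) the input's days.
#' @param site A [site_record] (for the velocity power law).
#' @param sw Optional raw shortwave [stream_ts] for the daily shortwave
#'   mean (`NA` if omitted).
#' @return data.frame, one row per fitted date, with the 11 predictors.
#' @export
daily_predictors <- function(input, fit, site, sw = NULL) {
  cols <- c("doobs_daily_mean", "dosat_daily_mean", "wtr_daily_mean",
            "sw_daily_mean", "depth_daily_mean", "disch_daily_mean",
            "veloc_daily_mean", "dopsat_daily_amp", "daylight_hours",
            "reach_length_80")
  if (length(fit$dates) == 0L) {
    out <- c(list(date = as.Date(character(0))),
             stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(as.data.frame(out))
  }
  by_date <- function(x) {
    agg <- tapply(x, input$date, function(v) mean(v, na.rm = TRUE))
    data.frame(date = as.Date(names(agg)), value = as.numeric(agg))
  }
  pick <- function(df) df$value[match(fit$dates, df$date)]
  veloc <- velocity_from_discharge(input$discharge, site$veloc_coefs)
  psat <- percent_saturation(input$DO.obs, input$DO.sat)
  amp <- tapply(psat, input$date, function(v)
    if (all(is.na(v))) NA_real_ else diff(range(v, na.rm = TRUE)))
  amp <- data.frame(date = as.Date(names(amp)), value = as.numeric(amp))
  res <- attr(input, "resolution")
  daylight <- tapply(input$light, input$date,
                     function(v) sum(v > 0, na.rm = TRUE) * res / 60)
  daylight <- data.frame(date = as.Date(names(daylight)),
                         value = as.numeric(daylight))
  swdaily <- if (!is.null(sw))
    daily_aggregate(sw, "mean", site$longitude) else NULL

  k50 <- fit$daily[fit$daily$parameter == "K600", c("date", "q50")]
  tmean <- pick(by_date(input$temp.water))
  vmean_md <- pick(by_date(veloc)) * 86400  # m s-1 -> m d-1
  ko2 <- K600_to_KO2(pmax(k50$q50[match(fit$dates, k50$date)], 0), tmean)
  L <- ifelse(vmean_md > 0 & ko2 > 0,
              -log(1 - 0.8) * vmean_md / ko2, NA_real_)
  data.frame(
    date = fit$dates,
    doobs_daily_mean = pick(by_date(input$DO.obs)),
    dosat_daily_mean = pick(by_date(input$DO.sat)),
    wtr_daily_mean = tmean,
    sw_daily_mean = if (is.null(swdaily)) NA_real_ else pick(swdaily),
    depth_daily_mean = pick(by_date(input$depth)),
    disch_daily_mean = pick(by_date(input$discharge)),
    veloc_daily_mean = pick(by_date(veloc)),
    dopsat_daily_amp = pick(amp),
    daylight_hours = pick(daylight),
    reach_length_80 = L)
}
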