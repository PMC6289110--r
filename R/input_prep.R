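#' Split an oxygen series into uniform-resolution chunks
#'
#' Metabolism models require a single temporal resolution, but long sensor
#' deployments often change logging interval (e.g. hourly for several years,
#' then every 15 minutes). This splits a series into maximal chunks of
#' constant nominal timestep. Resolution changes must be persistent to start
#' a new chunk: runs of a new timestep shorter than `min_run` intervals
#' (isolated missing timestamps, single-point glitches) are absorbed into the
#' surrounding chunk. The observation at a resolution change closes the old
#' chunk; the next one opens the new chunk.
#'
#' @param ts A [stream_ts].
#' @param min_run Minimum number of consecutive equal timesteps that counts
#'   as a persistent resolution (default 12).
#' @return List of [stream_ts] chunks, ordered and non-overlapping.
#' @export
split_by_resolution <- function(ts, min_run = 12) {
  stopifnot(inherits(ts, "stream_ts"))
  t <- ts$data$DateTime
  n <- length(t)
  if (n < min_run + 1L) return(list(ts))
  d <- round(diff(as.numeric(t)) / 60, 6)
  r <- rle(d)
  run_start <- cumsum(r$lengths) - r$lengths + 1L  # index into d
  persistent <- r$lengths >= min_run
  if (!any(persistent)) return(list(ts))
  pidx <- which(persistent)
  cur <- r$values[pidx[1L]]
  breaks <- integer(0)  # row index where a new chunk begins
  for (j in pidx[-1L]) {
    if (r$values[j] != cur) {
      breaks <- c(breaks, run_start[j] + 1L)
      cur <- r$values[j]
    }
  }
  bounds <- c(1L, breaks, n + 1L)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    rows <- bounds[i]:(bounds[i + 1L] - 1L)
    stream_ts(ts$site_id, ts$variable, t[rows], ts$data$value[rows])
  })
}

# gap intervals (seconds since epoch) of a series longer than max_gap hours,
# including the open intervals before the first and after the last timestamp
long_gaps <- function(datetime, max_gap_hours) {
  tn <- as.numeric(datetime)
  d <- diff(tn)
  idx <- which(d > max_gap_hours * 3600)
  rbind(c(-Inf, tn[1L]),
        cbind(tn[idx], tn[idx + 1L]),
        c(tn[length(tn)], Inf))
}

overlaps_window <- function(gaps, win_start, win_end, tol = 1) {
  any(gaps[, 1L] < win_end - tol & gaps[, 2L] > win_start + tol)
}

#' Merge input variables onto the oxygen timestamps
#'
#' Builds the per-site model-input table: all non-oxygen variables are
#' linearly interpolated onto the oxygen timestamps, filling gaps of at most
#' `max_gap_hours`. Any metabolism day (04:00-03:59 mean solar) whose window
#' overlaps a gap longer than `max_gap_hours` in any variable is flagged
#' invalid (`gap>3h`) -- the whole 24-h period is excluded from fitting. Days
#' whose windows extend beyond the span of the oxygen record (chunk edges)
#' are flagged `incomplete_window`.
#'
#' Rows are laid on the full uniform grid of each day's window so that the
#' timestep is constant; oxygen observations missing from short (allowed)
#' gaps appear as `NA` in `DO.obs`.
#'
#' @param o2 [stream_ts] of dissolved oxygen (mg L-1), uniform resolution
#'   (one chunk from [split_by_resolution]).
#' @param others Named list of [stream_ts] with names `DO.sat`, `depth`,
#'   `temp.water`, `light`, `discharge` (units mg L-1, m, degC,
#'   umol m-2 s-1, m3 s-1).
#' @param longitude Site longitude (decimal degrees east) for the mean-solar
#'   day windows.
#' @param max_gap_hours Longest fillable gap, hours (strictly greater
#'   excludes the day). Default 3.
#' @param aux_gap Optional named list mapping a variable name in `others` to
#'   a [stream_ts] whose timestamps define that variable's gaps (e.g. the raw
#'   shortwave series behind a merged light product).
#' @return List with `input` (a `metab_input` data.frame: `solar.time`,
#'   `date`, `DO.obs`, `DO.sat`, `depth`, `temp.water`, `light`,
#'   `discharge`; attribute `resolution` in minutes) and `validity` (a
#'   data.frame `date`, `valid`, `reason` with one row per candidate date;
#'   reasons: `none`, `gap>3h`, `incomplete_window`).
#' @export
merge_and_interpolate <- function(o2, others, longitude, max_gap_hours = 3,
                                  aux_gap = NULL) {
  stopifnot(inherits(o2, "stream_ts"))
  need <- c("DO.sat", "depth", "temp.water", "light", "discharge")
  if (!all(need %in% names(others)))
    stop("others must contain: ", paste(need, collapse = ", "))
  res_s <- o2$resolution * 60
  solar <- convert_UTC_to_solartime(o2$data$DateTime, longitude, "mean")
  sn <- as.numeric(solar)
  dates <- sort(unique(metab_date(solar)))
  if (length(dates) == 0L) return(list(input = NULL, validity = NULL))

  gap_o2 <- long_gaps(solar, max_gap_hours)
  gap_var <- lapply(need, function(v) {
    src <- if (!is.null(aux_gap[[v]])) aux_gap[[v]] else others[[v]]
    long_gaps(convert_UTC_to_solartime(src$data$DateTime, longitude, "mean"),
              max_gap_hours)
  })
  names(gap_var) <- need

  interp <- lapply(need, function(v) {
    ts <- others[[v]]
    tv <- as.numeric(convert_UTC_to_solartime(ts$data$DateTime, longitude,
                                              "mean"))
    ok <- !is.na(ts$data$value)
    if (sum(ok) < 2L) stop("variable ", v, " has fewer than 2 values")
    function(x) approx(tv[ok], ts$data$value[ok], xout = x, rule = 2)$y
  })
  names(interp) <- need

  rows <- list()
  validity <- data.frame(date = dates, valid = TRUE,
                         reason = "none", stringsAsFactors = FALSE)
  span <- range(sn)
  for (i in seq_along(dates)) {
    win_start <- as.numeric(as.POSIXct(paste(dates[i], "04:00:00"),
                                       tz = "UTC"))
    win_end <- win_start + 86400
    grid <- seq(win_start, win_end - res_s, by = res_s)
    if (win_start < span[1L] - 1 || (win_end - res_s) > span[2L] + 1) {
      validity$valid[i] <- FALSE
      validity$reason[i] <- "incomplete_window"
    } else if (overlaps_window(gap_o2, win_start, win_end - res_s) ||
               any(vapply(gap_var, overlaps_window, logical(1),
                          win_start, win_end - res_s))) {
      validity$valid[i] <- FALSE
      validity$reason[i] <- "gap>3h"
    }
    obs <- o2$data$value[match(grid, sn)]
    rows[[i]] <- data.frame(
      solar.time = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
      date = dates[i],
      DO.obs = obs,
      DO.sat = interp$DO.sat(grid),
      depth = interp$depth(grid),
      temp.water = interp$temp.water(grid),
      light = interp$light(grid),
      discharge = interp$discharge(grid))
  }
  input <- do.call(rbind, rows)
  attr(input, "resolution") <- o2$resolution
  class(input) <- c("metab_input", "data.frame")
  list(input = input, validity = validity)
}

#' Flag days without entirely positive flow
#'
#' Metabolism is only estimated for days with entirely positive flow,
#' avoiding intermittent or tidally reversing conditions. Any still-valid day
#' whose window contains a discharge observation `<= 0` is flagged
#' `nonpositive_flow`; already-invalid days keep their primary reason.
#'
#' @param input A `metab_input` data.frame (from [merge_and_interpolate]).
#' @param validity The matching validity data.frame.
#' @return Updated validity data.frame.
#' @export
filter_positive_flow <- function(input, validity) {
  if (!"discharge" %in% names(input)) stop("input lacks a discharge column")
  bad_dates <- unique(input$date[!is.na(input$discharge) &
                                   input$discharge <= 0])
  hit <- validity$valid & validity$date %in% bad_dates
  validity$valid[hit] <- FALSE
  validity$reason[hit] <- "nonpositive_flow"
  validity
}

#' Prepare model inputs from raw site series
#'
#' Full input-preparation chain for one site: splits the oxygen record into
#' uniform-resolution chunks, derives the forcing variables (oxygen
#' saturation from water temperature and barometric pressure; depth,
#' velocity-ready discharge in m3 s-1 via hydraulic geometry; merged PPFD
#' from modeled clear-sky light and shortwave radiation), interpolates
#' everything onto the oxygen timestamps, and applies the gap and
#' positive-flow day filters.
#'
#' @param site A [site_record].
#' @param raws Named list of raw [stream_ts]: `doobs` (mg L-1), `wtr`
#'   (degC), `disch` (ft3 s-1), `baro` (Pa), `sw` (W m-2).
#' @param max_gap_hours Longest fillable gap, hours. Default 3.
#' @param min_run Persistence threshold for [split_by_resolution].
#' @return List of chunks; each chunk is a list with `input`, `validity`,
#'   and `resolution` (minutes).
#' @export
prepare_model_input <- function(site, raws, max_gap_hours = 3, min_run = 12) {
  stopifnot(inherits(site, "site_record"))
  need <- c("doobs", "wtr", "disch", "baro", "sw")
  if (!all(need %in% names(raws)))
    stop("raws must contain: ", paste(need, collapse = ", "))
  chunks <- split_by_resolution(raws$doobs, min_run = min_run)

  q_cms <- cfs_to_cms(raws$disch$data$value)
  disch_ts <- stream_ts(site$site_id, "disch_cms", raws$disch$data$DateTime,
                        q_cms, raws$disch$resolution)
  depth_ts <- stream_ts(site$site_id, "depth_calcDisch",
                        raws$disch$data$DateTime,
                        depth_from_discharge(q_cms, site$depth_coefs),
                        raws$disch$resolution)
  par_sw <- stream_ts(site$site_id, "par_calcSw", raws$sw$data$DateTime,
                      convert_SW_to_PAR(raws$sw$data$value),
                      raws$sw$resolution)

  lapply(chunks, function(o2) {
    t_o2 <- o2$data$DateTime
    wtr_i <- approx(as.numeric(raws$wtr$data$DateTime), raws$wtr$data$value,
                    xout = as.numeric(t_o2), rule = 2)$y
    baro_i <- approx(as.numeric(raws$baro$data$DateTime),
                     raws$baro$data$value,
                     xout = as.numeric(t_o2), rule = 2)$y
    dosat_ts <- stream_ts(site$site_id, "dosat_calcGGbts", t_o2,
                          as.numeric(calc_DO_sat(wtr_i, baro_i)),
                          o2$resolution)
    app_solar <- convert_UTC_to_solartime(t_o2, site$longitude, "apparent")
    par_lat <- stream_ts(site$site_id, "par_calcLat", t_o2,
                         calc_light(app_solar, site$latitude), o2$resolution)
    light_ts <- calc_light_merged(par_lat, par_sw)

    merged <- merge_and_interpolate(
      o2,
      others = list(DO.sat = dosat_ts, depth = depth_ts,
                    temp.water = raws$wtr, light = light_ts,
                    discharge = disch_ts),
      longitude = site$longitude, max_gap_hours = max_gap_hours,
      aux_gap = list(DO.sat = raws$wtr, light = raws$sw))
    merged$validity <- filter_positive_flow(merged$input, merged$validity)
    list(input = merged$input, validity = merged$validity,
         resolution = o2$resolution)
  })
}
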