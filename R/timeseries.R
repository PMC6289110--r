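#' Site metadata record
#'
#' Static metadata for one monitoring site: coordinates, altitude, and the
#' at-a-station hydraulic-geometry coefficients used to convert discharge to
#' mean depth (`depth = c * Q^f`) and velocity (`velocity = k * Q^m`), with
#' discharge in m3 s-1. Optional distances to upstream structures (canals,
#' dams, permitted discharge points) support interference screening.
#'
#' @param site_id Character site identifier.
#' @param latitude Decimal degrees north, in `[-90, 90]`.
#' @param longitude Decimal degrees east (negative west), in `[-180, 180]`.
#' @param altitude Site elevation, m above datum.
#' @param depth_coefs Named numeric `c(c = , f = )`; `c` in m, `f`
#'   dimensionless; `c > 0`.
#' @param veloc_coefs Named numeric `c(k = , m = )`; `k` in m s-1; `k > 0`.
#' @param structure_distances Optional named list or vector with any of
#'   `canal`, `dam`, `npdes`: distance (m) to the nearest upstream structure
#'   of that type. `NULL` means no structure information.
#' @return An object of class `site_record`.
#' @export
site_record <- function(site_id, latitude, longitude, altitude,
                        depth_coefs = c(c = 0.4, f = 0.25),
                        veloc_coefs = c(k = 0.35, m = 0.25),
                        structure_distances = NULL) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  if (!is.finite(latitude) || latitude < -90 || latitude > 90)
    stop("latitude must be in [-90, 90]")
  if (!is.finite(longitude) || longitude < -180 || longitude > 180)
    stop("longitude must be in [-180, 180]")
  if (!is.finite(altitude)) stop("altitude must be finite")
  if (!all(c("c", "f") %in% names(depth_coefs)) || depth_coefs[["c"]] <= 0)
    stop("depth_coefs must be c(c = , f = ) with c > 0")
  if (!all(c("k", "m") %in% names(veloc_coefs)) || veloc_coefs[["k"]] <= 0)
    stop("veloc_coefs must be c(k = , m = ) with k > 0")
  structure(list(site_id = site_id, latitude = latitude,
                 longitude = longitude, altitude = altitude,
                 depth_coefs = depth_coefs, veloc_coefs = veloc_coefs,
                 structure_distances = structure_distances),
            class = "site_record")
}

#' Time-series container
#'
#' One site-variable time series: UTC timestamps, values, and a nominal
#' temporal resolution in minutes (inferred as the modal timestep when not
#' supplied). Timestamps must be strictly increasing.
#'
#' @param site_id Character site identifier.
#' @param variable Variable name (e.g. `"doobs_nwis"`, `"wtr_nwis"`,
#'   `"disch_nwis"`, `"baro_nldas"`, `"sw_nldas"`, `"par_calcLatSw"`).
#' @param datetime `POSIXct` timestamps in UTC, strictly increasing.
#' @param value Numeric values (units fixed per variable name).
#' @param resolution Nominal step in minutes; inferred if `NULL`.
#' @return An object of class `stream_ts`, a list with elements `site_id`,
#'   `variable`, `data` (data.frame with `DateTime`, `value`) and
#'   `resolution`.
#' @export
stream_ts <- function(site_id, variable, datetime, value, resolution = NULL) {
  stopifnot(inherits(datetime, "POSIXct"), length(datetime) == length(value))
  if (length(datetime) > 1L) {
    dt <- diff(as.numeric(datetime))
    if (any(dt <= 0)) stop("timestamps must be strictly increasing (no duplicates)")
    if (is.null(resolution)) resolution <- modal_step_minutes(datetime)
  }
  if (is.null(resolution)) resolution <- NA_real_
  attr(datetime, "tzone") <- "UTC"
  structure(list(site_id = site_id, variable = variable,
                 data = data.frame(DateTime = datetime, value = as.numeric(value)),
                 resolution = resolution),
            class = "stream_ts")
}

#' @export
print.stream_ts <- function(x, ...) {
  cat(sprintf("<stream_ts> %s / %s: %d obs, %g-min resolution, %s to %s\n",
              x$site_id, x$variable, nrow(x$data), x$resolution,
              format(min(x$data$DateTime), "%Y-%m-%d %H:%M", tz = "UTC"),
              format(max(x$data$DateTime), "%Y-%m-%d %H:%M", tz = "UTC")))
  invisible(x)
}

# modal timestep in minutes
modal_step_minutes <- function(datetime) {
  d <- round(diff(as.numeric(datetime)) / 60, 6)
  as.numeric(names(sort(table(d), decreasing = TRUE))[1L])
}

#' Read a site-variable time-series file
#'
#' Reads one tab-delimited two-column file (`DateTime` in ISO-8601 UTC,
#' `value`), the per-site-variable layout of sensor-network data releases.
#' The site id and variable name are parsed from a filename of the form
#' `<siteid>_<variable>.tsv`; the nominal resolution is inferred from the
#' modal timestep.
#'
#' @param path Path to a `.tsv` file.
#' @return A [stream_ts].
#' @export
read_timeseries <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("DateTime", "value") %in% names(d)))
    stop("expected columns DateTime and value in ", path)
  t <- as.POSIXct(d$DateTime, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(t)) {
    bad <- which(is.na(t))[1L]
    stop(sprintf("malformed timestamp at line %d of %s: '%s'",
                 bad + 1L, path, d$DateTime[bad]))
  }
  v <- suppressWarnings(as.numeric(d$value))
  fname <- sub("\\.tsv$", "", basename(path))
  site_id <- sub("_.*$", "", fname)
  variable <- sub("^[^_]*_", "", fname)
  stream_ts(site_id, variable, t, v)
}

#' Write a site-variable time-series file
#'
#' Writes the tab-delimited two-column layout read by [read_timeseries]
#' (ISO-8601 UTC timestamps, full-precision values). File name is
#' `<siteid>_<variable>.tsv` under `dir`.
#'
#' @param ts A [stream_ts].
#' @param dir Output directory (created if needed).
#' @return The file path, invisibly.
#' @export
write_timeseries <- function(ts, dir) {
  stopifnot(inherits(ts, "stream_ts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(ts$site_id, "_", ts$variable, ".tsv"))
  out <- data.frame(
    DateTime = format(ts$data$DateTime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    value = format_num(ts$data$value))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic full-precision numeric formatting (digits = 15, no sci notation drift)
format_num <- function(x, digits = 15) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}
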