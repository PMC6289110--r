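# Tab-delimited writers/readers for the release-style output tables.
# Missing values are written as NA; the per-model bundle keeps full
# precision, the combined daily-estimates table rounds to 4 significant
# digits for diff-stability.

write_tsv <- function(df, path, digits = NA) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, inherits, logical(1), "Date")
  out <- df
  for (j in which(num)) {
    x <- df[[j]]
    if (!is.na(digits)) x <- signif(x, digits)
    out[[j]] <- format_num(x)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a release-style tab-delimited table
#'
#' Generic reader for the tables written by [write_model_bundle],
#' [write_diagnostics_table] and [write_daily_estimates]; `NA` strings
#' become missing values and `date`/`DateTime` columns are parsed.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_output_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  d
}

#' Write or read a prepared model-input table
#'
#' Tab-delimited round trip of a merged model-input table (one row per
#' timestep, one column per input variable) plus its day-validity table.
#'
#' @param input A `metab_input` data.frame.
#' @param validity The matching validity data.frame.
#' @param dir Output directory (created if needed).
#' @return `write_model_input` returns `dir` invisibly;
#'   `read_model_input` returns `list(input, validity)` with the
#'   `metab_input` class and resolution attribute restored.
#' @export
write_model_input <- function(input, validity, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- input
  tab$solar.time <- format(input$solar.time, "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
  write_tsv(as.data.frame(tab), file.path(dir, "input.tsv"))
  write_tsv(validity, file.path(dir, "validity.tsv"))
  invisible(dir)
}

#' @rdname write_model_input
#' @export
read_model_input <- function(dir) {
  inp <- read_output_table(file.path(dir, "input.tsv"))
  inp$solar.time <- as.POSIXct(inp$solar.time,
                               format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  attr(inp, "resolution") <- modal_step_minutes(inp$solar.time)
  class(inp) <- c("metab_input", "data.frame")
  val <- read_output_table(file.path(dir, "validity.tsv"))
  list(input = inp, validity = val)
}

#' Write the per-model output bundle
#'
#' Writes one model's results as four tab-delimited tables plus a metadata
#' text file in `dir`: `daily.tsv` (posterior summaries for GPP/ER/K600 by
#' date), `nodes.tsv` (K600~Q node summaries), `overall.tsv` (error SDs and
#' the daily-K600 deviation sd), `daily_msgs.tsv` (per-date exclusion
#' messages), and `metadata.txt` (run settings and timing).
#'
#' @param fit A `metab_fit`.
#' @param dir Output directory (created if needed).
#' @param model_id Model identifier recorded in the metadata.
#' @param validity Optional validity table for the exclusion messages.
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(fit, dir, model_id = "model",
                               validity = NULL) {
  stopifnot(inherits(fit, "metab_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(fit$daily, file.path(dir, "daily.tsv"))
  if (!is.null(fit$nodes))
    write_tsv(fit$nodes, file.path(dir, "nodes.tsv"))
  write_tsv(fit$overall, file.path(dir, "overall.tsv"))
  msgs <- if (is.null(validity)) {
    data.frame(date = fit$dates, message = "fitted")
  } else {
    data.frame(date = validity$date,
               message = ifelse(validity$valid, "fitted",
                                paste0("excluded: ", validity$reason)))
  }
  write_tsv(msgs, file.path(dir, "daily_msgs.tsv"))
  writeLines(c(
    paste0("model_id: ", model_id),
    paste0("model: ", fit$model),
    paste0("chains: ", fit$mcmc$chains),
    paste0("warmup: ", fit$mcmc$warmup),
    paste0("saved: ", fit$mcmc$saved),
    paste0("thin: ", fit$mcmc$thin),
    paste0("seed: ", fit$mcmc$seed),
    paste0("rerun: ", fit$rerun),
    paste0("runtime_s: ", fit$mcmc$runtime_s),
    paste0("n_days: ", length(fit$dates))),
    file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Read a per-model output bundle
#'
#' Reconstructs a `metab_fit` (posterior summaries, node pool, run
#' metadata; without raw draws) from the tables written by
#' [write_model_bundle].
#'
#' @param dir Bundle directory.
#' @return A `metab_fit`.
#' @export
read_model_bundle <- function(dir) {
  daily <- read_output_table(file.path(dir, "daily.tsv"))
  overall <- read_output_table(file.path(dir, "overall.tsv"))
  meta_lines <- readLines(file.path(dir, "metadata.txt"))
  meta <- strsplit(meta_lines, ": ", fixed = TRUE)
  meta <- stats::setNames(lapply(meta, `[`, 2L),
                          vapply(meta, `[`, character(1), 1L))
  nodes <- NULL; pool <- NULL
  if (file.exists(file.path(dir, "nodes.tsv"))) {
    nodes <- read_output_table(file.path(dir, "nodes.tsv"))
    skd <- overall$q50[overall$parameter == "sigma_K600_daily"]
    pool <- k600_pool(nodes$lnQ, nodes$q50,
                      if (length(skd)) skd else NA_real_)
  }
  structure(list(
    daily = daily, nodes = nodes, overall = overall, pool = pool,
    dates = sort(unique(daily$date)),
    lnQ = NULL, model = meta$model, draws = NULL,
    mcmc = list(chains = as.integer(meta$chains),
                warmup = as.integer(meta$warmup),
                saved = as.integer(meta$saved),
                thin = as.integer(meta$thin),
                seed = as.integer(meta$seed),
                runtime_s = as.numeric(meta$runtime_s)),
    config = NULL,
    rerun = identical(meta$rerun, "TRUE")), class = "metab_fit")
}

#' Write the one-row-per-model diagnostics table
#'
#' Combines per-model assessment records ([assess_model]) into a single
#' tab-delimited table, one row per model.
#'
#' @param records data.frame of assessment records (rbind of
#'   [assess_model] outputs, optionally with extra id columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics_table <- function(records, path) {
  write_tsv(records, path)
}

#' Write the combined daily estimates and predictors table
#'
#' One row per site-date: the 2.5/50/97.5 percentiles, R-hat and n_eff for
#' GPP, ER and K600, followed by the daily predictor variables. Percentile
#' ordering is checked on write. Values are rounded to 4 significant
#' digits.
#'
#' @param fit A pooled `metab_fit`.
#' @param predictors data.frame from [daily_predictors].
#' @param path Output file.
#' @param site_id Site identifier column value.
#' @return `path`, invisibly.
#' @export
write_daily_estimates <- function(fit, predictors, path,
                                  site_id = "site") {
  wide <- lapply(c("GPP", "ER", "K600"), function(p) {
    d <- fit$daily[fit$daily$parameter == p, ]
    d <- d[match(fit$dates, d$date), ]
    if (any(d$q2.5 > d$q50 | d$q50 > d$q97.5, na.rm = TRUE))
      stop("percentile ordering violated for ", p)
    out <- d[, c("q2.5", "q50", "q97.5", "Rhat", "n_eff")]
    names(out) <- paste0(p, c("_2.5pct", "_50pct", "_97.5pct", "_Rhat",
                              "_neff"))
    out
  })
  tab <- cbind(data.frame(site_id = rep_len(site_id, length(fit$dates)),
                          date = fit$dates),
               do.call(cbind, wide),
               predictors[match(fit$dates, predictors$date),
                          setdiff(names(predictors), "date"),
                          drop = FALSE])
  rownames(tab) <- NULL
  write_tsv(tab, path, digits = 4)
}

#' Read or write a model-run configuration
#'
#' YAML round trip of the per-model run configuration (site, variable
#' source preferences, prior overrides, MCMC settings, seed), mirroring a
#' one-row-per-model configuration table.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @return `read_run_config` returns the list; `write_run_config` returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
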