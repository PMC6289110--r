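#!/usr/bin/env Rscript
# Build the synthetic study site: 14 complete metabolism days of 15-minute
# oxygen, temperature and discharge plus hourly pressure and shortwave
# radiation, with known true daily GPP, ER and K600. Raw series are written
# in the per-site-variable release layout; the latent truth is kept
# alongside for the final recovery report.

library(oxbow)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 42

out <- "results/synthetic_site"
dir.create(file.path(out, "timeseries"), recursive = TRUE,
           showWarnings = FALSE)

cfg <- synthetic_site_config(seed = seed)
g <- generate_site(cfg)

for (v in names(g$raws)) write_timeseries(g$raws[[v]], file.path(out, "timeseries"))

write.table(format(g$truth$daily, digits = 10),
            file.path(out, "truth_daily.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

site <- g$site
write_run_config(list(
  site_id = site$site_id, latitude = site$latitude,
  longitude = site$longitude, altitude = site$altitude,
  depth_coefs = as.list(site$depth_coefs),
  veloc_coefs = as.list(site$veloc_coefs),
  # distances (m) to the nearest upstream structures, for the
  # interference screening step
  structure_distances = list(canal = 800, dam = 8000, npdes = NA),
  seed = seed), file.path(out, "site.yml"))

cat(sprintf("site %s: %d days at %d-min resolution, %d oxygen observations\n",
            site$site_id, cfg$n_days, cfg$resolution_min,
            nrow(g$raws$doobs$data)))
cat(sprintf("true daily GPP %.1f-%.1f, ER %.1f-%.1f g O2 m-2 d-1, K600 %.1f-%.1f d-1\n",
            min(g$truth$daily$GPP), max(g$truth$daily$GPP),
            min(g$truth$daily$ER), max(g$truth$daily$ER),
            min(g$truth$daily$K600), max(g$truth$daily$K600)))
cat("raw series written under", file.path(out, "timeseries"), "\n")
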