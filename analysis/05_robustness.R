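#!/usr/bin/env Rscript
# Stage 5 — robustness battery.
#
# Migration restriction (mothers whose residence covers conception through
# interview), postnatal-exposure controls, the cold placebo, alternative
# fixed-effect schemes, country exclusion, and the 5-year reference-window
# variant (recomputing thresholds and exposures from the stored climate).

suppressMessages({library(heatnatal); library(data.table)})

births <- fread("results/births.csv")
expo <- fread("results/exposures.csv")
clusters <- fread("results/clusters.csv")
a <- merge_tables(births, expo, clusters)

res <- list()
for (v in c("migration", "postnatal", "cold", "fe_country_month",
            "fe_cell1_month")) {
  message("robustness: ", v, " ...")
  r <- run_robustness(a, v)
  res[[v]] <- r$results
  if (!is.null(r$n_kept)) {
    message(sprintf("  kept %d, dropped %d", r$n_kept, r$n_dropped))
  }
}
res$exclude <- run_robustness(a, "exclude_country", exclude = 1L)$results

message("cold placebo: ", sum(res$cold$p < 0.05), " of ",
        nrow(res$cold), " metrics significant at 5%")
message("postnatal terms significant: ",
        res$postnatal[grepl("^post_", term), sum(p < 0.05)], " of 8")

message("5-year reference window variant ...")
clim <- read_climate("results/climate.csv")
precip <- fread("results/precip.csv")
wt <- climate_wetbulb(clim)
world <- list(config = world_config(seed = 1L, n_countries = 3L,
                                    clusters_per_country = 50L,
                                    births_per_cluster = 60L,
                                    lon_range = c(10, 16), lat_range = c(-6, 0)),
              wetbulb = wt, climate = list(precip = precip),
              births = births, clusters = clusters, analysis = a)
r5 <- run_window_variant(world, k = 5, metrics = "cumulative")
res$window_k5 <- r5$results
message(sprintf("  k=5 births analyzed: %d (of %d)", r5$results$n[1], nrow(a)))

out <- rbindlist(res, fill = TRUE)
fwrite(out, "results/regressions_robustness.csv")
write_manifest(run_manifest(files = "results/regressions_robustness.csv",
                            counts = list(models = nrow(out))),
               "results/manifest_05.json")
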