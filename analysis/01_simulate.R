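#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study world and write its data files.
#
# A reduced-scale survey world: 3 countries x 50 clusters x 60 births
# (9,000 births, Oct 2006 - Jun 2020) on daily climate 2003-2020, with the
# default planted truth (0.03 extra deaths per 1,000 births per deg C x day
# of 90th-percentile cumulative wet-bulb heat). Downstream stages consume
# only the files written here.

suppressMessages({library(heatnatal); library(data.table)})

seed <- 20260930L %% 100000L
dir.create("results", showWarnings = FALSE)

cfg <- world_config(seed = seed, n_countries = 3L, clusters_per_country = 50L,
                    births_per_cluster = 60L, lon_range = c(10, 16),
                    lat_range = c(-6, 0))
truth <- truth_params()

message("simulating world ...")
world <- simulate_world(cfg, truth, keep_climate = TRUE)

write_climate(world$climate$daily, "results/climate.csv")
fwrite(world$climate$precip, "results/precip.csv")
fwrite(world$clusters, "results/clusters.csv")
fwrite(world$births, "results/births.csv")
jsonlite::write_json(unclass(truth), "results/truth.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
jsonlite::write_json(cfg[setdiff(names(cfg), c("lon_range", "lat_range",
                                               "years", "birth_start", "birth_end"))],
                     "results/config_echo.json", auto_unbox = TRUE, pretty = TRUE)

man <- run_manifest(
  files = c("results/climate.csv", "results/precip.csv",
            "results/clusters.csv", "results/births.csv", "results/truth.json"),
  seeds = list(world = cfg$seed),
  counts = list(clusters = nrow(world$clusters), births = nrow(world$births),
                climate_rows = nrow(world$climate$daily),
                exposure_rejects = nrow(world$rejects)))
write_manifest(man, "results/manifest_01.json")

message(sprintf("world: %d clusters, %d births, mortality %.1f/1000, clip %.4f",
                nrow(world$clusters), nrow(world$births),
                1000 * mean(world$births$neonatal_death), world$clip_fraction))
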