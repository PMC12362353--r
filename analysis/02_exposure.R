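#!/usr/bin/env Rscript
# Stage 2 — wet-bulb conversion, percentile thresholds, gestational exposure.
#
# Reads the climate and survey files written by stage 1, converts to wet-bulb
# temperature, builds the rolling 3-year seasonal percentile thresholds per
# cluster pixel, and writes one exposure record per birth (16 gestational
# heat/cold metrics, their postnatal counterparts, and window-mean
# precipitation) plus a rejects report and a metadata sidecar.

suppressMessages({library(heatnatal); library(data.table)})

clim <- read_climate("results/climate.csv")
precip <- fread("results/precip.csv")
clusters <- fread("results/clusters.csv")
births <- fread("results/births.csv")

message("wet-bulb conversion ...")
wt <- climate_wetbulb(clim)
message(sprintf("%d daily readings, %d outside the Stull validity envelope",
                nrow(wt), attr(wt, "n_out_of_envelope")))

years <- sort(unique(wt$year))
first_birth <- births[, min(ym_index(birth_year, birth_month))]
target_years <- ym_year(first_birth - 9L):max(births$birth_year)
message("thresholds for ", length(target_years), " target years ...")
thr <- build_thresholds(wt, target_years, k = 3L)
fwrite(thr, "results/thresholds.csv")

message("exposure records ...")
expo <- compute_exposures(births, clusters, wt, thr, precip)
fwrite(expo$exposures, "results/exposures.csv")
fwrite(expo$rejects, "results/exposure_rejects.csv")
jsonlite::write_json(expo$meta, "results/exposure_meta.json",
                     auto_unbox = TRUE, pretty = TRUE)

man <- run_manifest(
  files = c("results/thresholds.csv", "results/exposures.csv",
            "results/exposure_rejects.csv"),
  counts = list(births_in = nrow(births), exposed = nrow(expo$exposures),
                rejects = nrow(expo$rejects)))
write_manifest(man, "results/manifest_02.json")

message(sprintf("exposed %d of %d births (%d rejects); mean cum heat (P90) %.1f degC-days, mean heat days (P90) %.1f",
                nrow(expo$exposures), nrow(births), nrow(expo$rejects),
                mean(expo$exposures$cum_heat_90), mean(expo$exposures$heat_days_90)))
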