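Package: heatnatal
Title: In Utero Extreme-Heat Exposure Metrics and Neonatal Mortality Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the effect of in utero extreme-heat exposure on
    neonatal mortality. Converts daily dry-bulb temperature and relative humidity
    to wet-bulb temperature (Stull approximation), builds location- and
    season-specific percentile thresholds from rolling reference windows,
    computes gestational and postnatal cumulative-exceedance and
    exceedance-day exposure metrics for heat and cold, and estimates
    linear-probability models with high-dimensional absorbed fixed effects and
    cluster-robust (CR1) standard errors. A synthetic-world generator with
    planted effects supports end-to-end validation and parameter-recovery
    simulation, and a study pipeline reproduces the full regression battery:
    baseline, rural/urban split, prenatal-checkups mechanism, subgroup
    heterogeneity, and robustness variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
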