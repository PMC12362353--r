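# Shared Monte Carlo computations for the validation suite. Each stat set is
# computed once per session and cached; replicates are distinct climate
# worlds crossed with fresh outcome draws (see helper-worlds.R).

.sim_cache <- new.env(parent = emptyenv())

N_FULL_WORLDS <- 20L
REDRAWS_FULL <- 5L    # 100 replicates for recovery/heterogeneity
N_SMALL_WORLDS <- 20L
REDRAWS_SMALL <- 10L  # 200 replicates for size/placebo calibration

# Recovery of the planted beta on the default world, plus the equal-multiplier
# water interaction fitted on the same replicates.
recovery_stats <- function() {
  if (!exists("recovery", .sim_cache)) {
    truth <- truth_params()
    est <- se <- lo <- hi <- numeric(0)
    inter_lo <- inter_hi <- numeric(0)
    r <- 0L
    for (i in seq_len(N_FULL_WORLDS)) {
      w <- full_world(i)
      for (j in seq_len(REDRAWS_FULL)) {
        r <- r + 1L
        a <- redraw_outcomes(w, truth, seed = 30000L + r)
        f <- fit_fe_lpm(fe_spec("neonatal_death", "cum_heat_90",
                                default_controls(), scale_outcome = TRUE), a)
        row <- f$table[f$table$term == "cum_heat_90", ]
        est[r] <- row$estimate; se[r] <- row$se
        lo[r] <- row$ci_lo; hi[r] <- row$ci_hi
        sg <- run_subgroup(a, "water", metrics = "cumulative", percentiles = 90)
        inter_lo[r] <- sg$interaction$ci_lo
        inter_hi[r] <- sg$interaction$ci_hi
      }
    }
    assign("recovery", list(truth = truth$beta_heat, est = est, se = se,
                            lo = lo, hi = hi,
                            inter_lo = inter_lo, inter_hi = inter_hi),
           envir = .sim_cache)
  }
  get("recovery", .sim_cache)
}

# Stratified batteries under planted heterogeneity: rural-only effect and a
# doubled unimproved-water effect, on the same cached worlds.
heterogeneity_stats <- function() {
  if (!exists("heterogeneity", .sim_cache)) {
    truths <- list(rural = truth_params(mult_urban = 0),
                   water = truth_params(mult_unimproved_water = 2))
    rank_rural <- rank_water <- logical(0)
    r <- 0L
    for (i in seq_len(N_FULL_WORLDS)) {
      w <- full_world(i)
      for (j in seq_len(REDRAWS_FULL)) {
        r <- r + 1L
        a <- redraw_outcomes(w, truths$rural, seed = 40000L + r)
        rs <- run_residence_split(a, metrics = "cumulative", percentiles = 90)
        tab <- rs$results
        rank_rural[r] <- tab[tab$stratum == "rural", ]$estimate >
          tab[tab$stratum == "urban", ]$estimate
        a <- redraw_outcomes(w, truths$water, seed = 50000L + r)
        sg <- run_subgroup(a, "water", metrics = "cumulative", percentiles = 90)
        tab <- sg$results
        rank_water[r] <- tab[tab$stratum == "unimproved", ]$estimate >
          tab[tab$stratum == "improved", ]$estimate
      }
    }
    assign("heterogeneity", list(rank_rural = rank_rural, rank_water = rank_water),
           envir = .sim_cache)
  }
  get("heterogeneity", .sim_cache)
}

# Test size under the null (no heat effect) and the cold-placebo battery on a
# heat-only world, at reduced n.
size_stats <- function() {
  if (!exists("size", .sim_cache)) {
    null_truth <- truth_params(beta_heat = 0)
    heat_truth <- truth_params()
    heat_cols <- c(vapply(HEAT_PERCENTILES, function(p) metric_col("cumulative", p, "heat"), ""),
                   vapply(HEAT_PERCENTILES, function(p) metric_col("days", p, "heat"), ""))
    cold_cols <- c(vapply(COLD_PERCENTILES, function(p) metric_col("cumulative", p, "cold"), ""),
                   vapply(COLD_PERCENTILES, function(p) metric_col("days", p, "cold"), ""))
    rej_null <- matrix(NA, N_SMALL_WORLDS * REDRAWS_SMALL, length(heat_cols),
                       dimnames = list(NULL, heat_cols))
    rej_cold <- matrix(NA, N_SMALL_WORLDS * REDRAWS_SMALL, length(cold_cols),
                       dimnames = list(NULL, cold_cols))
    r <- 0L
    for (i in seq_len(N_SMALL_WORLDS)) {
      w <- small_world(i)
      for (j in seq_len(REDRAWS_SMALL)) {
        r <- r + 1L
        a <- redraw_outcomes(w, null_truth, seed = 60000L + r)
        for (col in heat_cols) {
          f <- fit_fe_lpm(fe_spec("neonatal_death", col, default_controls(),
                                  scale_outcome = TRUE), a)
          rej_null[r, col] <- f$table[f$table$term == col, ]$p < 0.05
        }
        a <- redraw_outcomes(w, heat_truth, seed = 70000L + r)
        for (col in cold_cols) {
          f <- fit_fe_lpm(fe_spec("neonatal_death", col, default_controls(),
                                  scale_outcome = TRUE), a)
          rej_cold[r, col] <- f$table[f$table$term == col, ]$p < 0.05
        }
      }
    }
    assign("size", list(null = colMeans(rej_null), cold = colMeans(rej_cold),
                        n_reps = r), envir = .sim_cache)
  }
  get("size", .sim_cache)
}
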