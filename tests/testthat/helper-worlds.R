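# Shared synthetic worlds for the simulation-based tests. Climate and
# exposure generation is the expensive stage and does not depend on the
# planted truth, so worlds are simulated once (memoised here) and reused
# across scenarios with fresh outcome draws.

.world_cache <- new.env(parent = emptyenv())

# Full-scale study world: 500 clusters, 50,000 births, defaults throughout.
full_world <- function(i) {
  key <- paste0("full", i)
  if (!exists(key, .world_cache)) {
    w <- simulate_world(world_config(seed = 1000L + i))
    assign(key, list(analysis = w$analysis, births = w$births,
                     clusters = w$clusters,
                     exposures = w$exposures[, c("birth_id", "cum_heat_90")],
                     truth = w$truth),
           envir = .world_cache)
  }
  get(key, .world_cache)
}

# Reduced-n world for size/placebo calibration: 150 clusters, 6,000 births.
small_world <- function(i) {
  key <- paste0("small", i)
  if (!exists(key, .world_cache)) {
    w <- simulate_world(world_config(
      seed = 2000L + i, n_countries = 3L, clusters_per_country = 50L,
      births_per_cluster = 40L, lon_range = c(10, 15), lat_range = c(-5, 0)))
    assign(key, list(analysis = w$analysis, births = w$births,
                     clusters = w$clusters,
                     exposures = w$exposures[, c("birth_id", "cum_heat_90")]),
           envir = .world_cache)
  }
  get(key, .world_cache)
}

# Tiny world with the daily climate kept, for per-day oracle checks.
toy_world <- function(seed = 42L) {
  key <- paste0("toy", seed)
  if (!exists(key, .world_cache)) {
    w <- simulate_world(world_config(
      seed = seed, n_countries = 2L, clusters_per_country = 6L,
      births_per_cluster = 15L, lon_range = c(10, 12), lat_range = c(-2, 0)),
      keep_climate = TRUE)
    assign(key, w, envir = .world_cache)
  }
  get(key, .world_cache)
}

# Fresh outcome draw on a cached world under a given truth; returns the
# analysis table with the outcome columns replaced.
redraw_outcomes <- function(world, truth, seed) {
  b2 <- assign_outcomes(world$births, world$clusters, world$exposures, truth,
                        seed = seed)
  a <- data.table::copy(world$analysis)
  stopifnot(nrow(a) == nrow(b2), all(a$birth_id == b2$birth_id))
  a[, `:=`(neonatal_death = b2$neonatal_death,
           prenatal_visits = b2$prenatal_visits,
           p_true = b2$p_true)]
  a
}
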