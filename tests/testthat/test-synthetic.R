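library(data.table)

small_cfg <- function(seed = 5L, ...) {
  world_config(seed = seed, n_countries = 2L, clusters_per_country = 10L,
               births_per_cluster = 20L, lon_range = c(10, 13),
               lat_range = c(-3, 0), ...)
}

test_that("the generator is fully deterministic given config and seed", {
  c1 <- generate_climate(small_cfg())
  c2 <- generate_climate(small_cfg())
  expect_identical(c1$daily, c2$daily)
  expect_identical(c1$precip, c2$precip)
  p1 <- generate_population(small_cfg())
  p2 <- generate_population(small_cfg())
  expect_identical(p1$births, p2$births)
  expect_identical(p1$clusters, p2$clusters)
  c3 <- generate_climate(small_cfg(seed = 6L))
  expect_false(identical(c1$daily$t, c3$daily$t))
})

test_that("clusters nest inside their 1- and 2-degree cells", {
  p <- generate_population(world_config(seed = 2, n_countries = 10,
                                        clusters_per_country = 20))
  expect_equal(nrow(p$clusters), 200L)
  expect_equal(p$clusters$cell2,
               grid_cell_id(p$clusters$lon, p$clusters$lat, 2))
  # nesting: the 1-degree cell's lower corner falls inside the 2-degree cell
  lon1 <- floor(p$clusters$lon); lat1 <- floor(p$clusters$lat)
  expect_equal(grid_cell_id(lon1, lat1, 2), p$clusters$cell2)
  lon05 <- floor(p$clusters$lon * 2) / 2; lat05 <- floor(p$clusters$lat * 2) / 2
  expect_equal(grid_cell_id(lon05, lat05, 1), p$clusters$cell1)
  expect_true(all(p$clusters$residence_type %in% c("rural", "urban")))
  p0 <- generate_population(small_cfg(fraction_urban = 0))
  expect_true(all(p0$clusters$residence_type == "rural"))
})

test_that("covariate marginals sit near their configured probabilities", {
  cfg <- world_config(seed = 77, n_countries = 5, clusters_per_country = 20,
                      births_per_cluster = 100)
  b <- generate_population(cfg)$births
  n <- nrow(b)
  for (chk in list(c(mean(b$gender), 0.512),
                   c(mean(b$mother_edu), 0.35),
                   c(mean(b$water_class == "improved"), 0.65),
                   c(mean(b$sanitation_class == "improved"), 0.4))) {
    se <- sqrt(chk[2] * (1 - chk[2]) / n)
    expect_lt(abs(chk[1] - chk[2]), 3 * se + 1e-12)
  }
  expect_true(all(b$mother_age >= 13 & b$mother_age <= 49))
  expect_true(all(b$interview_ym > ym_index(b$birth_year, b$birth_month)))
  expect_true(all(b$birth_order >= 1))
})

test_that("a zero-effect world reproduces the configured baseline mortality", {
  w <- toy_world()
  tr <- truth_params(beta_heat = 0, sd_cluster = 0, sd_year = 0,
                     sd_cellmonth = 0, b_male = 0, b_birth_order = 0,
                     b_age = 0, b_age_sq = 0, b_edu = 0, b_urban = 0)
  deaths <- integer(0)
  for (s in 1:40) {
    a <- redraw_outcomes(w, tr, seed = 7000 + s)
    deaths <- c(deaths, a$neonatal_death)
  }
  n <- length(deaths)
  se <- sqrt(0.029 * 0.971 / n)
  expect_lt(abs(mean(deaths) - 0.029), 3 * se)
})

test_that("planted linear predictor is recovered to machine precision", {
  # regressing the pre-Bernoulli probability (x1000) recovers beta_heat
  # exactly: every planted term is linear in the fitted model's columns
  w <- toy_world()
  a <- copy(w$analysis)
  a[, p1000 := p_true * 1000]
  f <- fit_fe_lpm(fe_spec("p1000", "cum_heat_90",
                          c("gender", "birth_order", "mother_age",
                            "mother_age_sq", "mother_edu")), a)
  expect_equal(f$table[term == "cum_heat_90", estimate], w$truth$beta_heat,
               tolerance = 1e-7)
  # planted covariate terms are linear in the controls, so they come back too
  expect_equal(f$table[term == "gender", estimate], w$truth$b_male * 1000,
               tolerance = 1e-6)
})

test_that("group multipliers plant exactly the advertised subgroup effects", {
  w <- toy_world()
  tr <- truth_params(mult_urban = 0)
  b <- assign_outcomes(w$births, w$clusters, w$exposures, tr, seed = 1)
  a <- copy(w$analysis)[, p1000 := b$p_true * 1000]
  # exact linear outcomes make the fits noiseless, so t statistics degenerate
  fu <- suppressWarnings(fit_fe_lpm(fe_spec("p1000", "cum_heat_90",
                           c("gender", "birth_order", "mother_age",
                             "mother_age_sq", "mother_edu"),
                           filter = quote(residence_type == "urban")), a))
  fr <- suppressWarnings(fit_fe_lpm(fe_spec("p1000", "cum_heat_90",
                           c("gender", "birth_order", "mother_age",
                             "mother_age_sq", "mother_edu"),
                           filter = quote(residence_type == "rural")), a))
  expect_equal(fu$table[term == "cum_heat_90", estimate], 0, tolerance = 1e-7)
  expect_equal(fr$table[term == "cum_heat_90", estimate], tr$beta_heat,
               tolerance = 1e-7)
})

test_that("checkups are independent of heat when the planted rate effect is zero", {
  w <- toy_world()
  tr <- truth_params(gamma_checkups = 0)
  a <- redraw_outcomes(w, tr, seed = 11)
  r <- cor(a$prenatal_visits, a$cum_heat_90)
  expect_lt(abs(r), 3 / sqrt(nrow(a)))
})

test_that("a warming trend raises heat days against a fixed baseline climatology", {
  # rolling reference windows adapt to a linear trend with a constant lag, so
  # trend-driven growth in exposure is measured against a fixed early-period
  # climatology (as in descriptive exposure trends)
  cfg <- small_cfg(seed = 12, trend = 1)
  wtd <- climate_wetbulb(generate_climate(cfg)$daily)
  thr <- build_thresholds(wtd, target_years = c(2007L, 2019L), percentiles = 90,
                          reference = "fixed", ref_years = 2003:2005)
  mo <- heatnatal:::monthly_exposure(wtd, thr)
  days <- mo[, .(days = sum(heat_days_90)), by = .(cell, year = ym_year(ym))]
  expect_gt(days[year == 2019, mean(days)], days[year == 2007, mean(days)])
})

test_that("degenerate truths are flagged through the clip fraction", {
  w <- toy_world()
  expect_error(
    assign_outcomes(w$births, w$clusters, w$exposures,
                    truth_params(alpha0 = -5), seed = 1),
    "degenerate truth")
  expect_warning(
    assign_outcomes(w$births, w$clusters, w$exposures,
                    truth_params(alpha0 = 0.001, b_male = -0.002), seed = 1),
    "clipped")
  expect_lt(toy_world()$clip_fraction, 0.001)
})
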