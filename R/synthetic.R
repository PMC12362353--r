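# Synthetic study world: climate cube, survey clusters, births, and outcomes
# from a planted linear-probability process.
#
# The world emulates the structure of a multi-country household-survey
# analysis at reduced scale: survey clusters nested in 2-degree grid cells
# nested in countries, births over October 2006 - June 2020, daily climate
# 2003-2020 with a seasonal cycle, day-to-day AR(1) noise and a warming
# trend. The outcome process is linear in exposure on the probability scale,
# so the planted per-1,000 coefficient is exactly the estimand of the fitted
# linear probability model.

#' Grid cell id from coordinates
#'
#' Half-open cells `[a, a + step)`; id encodes `(floor(lon/step),
#' floor(lat/step))` as a single integer, deterministic at boundaries.
#' @param lon,lat Decimal degrees.
#' @param step Cell size in degrees.
#' @return Integer cell id.
#' @export
grid_cell_id <- function(lon, lat, step) {
  ix <- as.integer(floor(lon / step))
  iy <- as.integer(floor(lat / step))
  (ix + 2000L) * 100000L + (iy + 2000L)
}

#' Configuration of the synthetic world
#'
#' Defaults give a reduced-scale study: 5 countries x 100 clusters x 100
#' births (~50,000 births) over a 10 x 10 degree tropical box, daily climate
#' 2003-2020. Climate parameters: `seasonal_amp` (deg C, half-range of the
#' annual cycle), `ar1` and `noise_sd` (day-to-day AR(1) anomaly: innovation
#' s.d. `noise_sd`, persistence `ar1`), `trend` (deg C per decade),
#' `rh_mean`/`rh_amp` (relative humidity cycle, percent).
#'
#' @param seed Master seed; all randomness derives from it.
#' @param n_countries,clusters_per_country,births_per_cluster Sizes.
#' @param lon_range,lat_range Box, decimal degrees.
#' @param grid_step Climate pixel size (degrees); must divide 2 evenly so
#'   that 1- and 2-degree cells nest.
#' @param years Calendar years of climate coverage.
#' @param seasonal_amp,ar1,noise_sd,trend,rh_mean,rh_amp,rh_sd Climate
#'   parameters (see above).
#' @param fraction_urban Probability a cluster is urban.
#' @param birth_start,birth_end First and last birth month, `c(year, month)`.
#' @param fraction_movers Fraction of mothers with short residence duration
#'   (for the migration-restriction variant).
#' @param confounded_seasonality If `TRUE`, the cell-by-birth-month outcome
#'   effects follow the seasonal temperature cycle instead of being iid,
#'   creating omitted-variable bias when those fixed effects are dropped.
#' @return A validated `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_countries = 5L,
                         clusters_per_country = 100L,
                         births_per_cluster = 100L,
                         lon_range = c(10, 20),
                         lat_range = c(-10, 0),
                         grid_step = 0.5,
                         years = 2003:2020,
                         seasonal_amp = 4,
                         ar1 = 0.9,
                         noise_sd = 2.5,
                         trend = 0.3,
                         rh_mean = 60,
                         rh_amp = 15,
                         rh_sd = 5,
                         fraction_urban = 0.3,
                         birth_start = c(2006L, 10L),
                         birth_end = c(2020L, 6L),
                         fraction_movers = 0.3,
                         confounded_seasonality = FALSE) {
  if (diff(range(lon_range)) <= 0 || diff(range(lat_range)) <= 0) {
    stop("degenerate lon/lat box", call. = FALSE)
  }
  if (abs(2 / grid_step - round(2 / grid_step)) > 1e-9) {
    stop("grid_step must divide 2 evenly so 1- and 2-degree cells nest", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_countries = as.integer(n_countries),
              clusters_per_country = as.integer(clusters_per_country),
              births_per_cluster = as.integer(births_per_cluster),
              lon_range = lon_range, lat_range = lat_range,
              grid_step = grid_step, years = as.integer(years),
              seasonal_amp = seasonal_amp, ar1 = ar1, noise_sd = noise_sd,
              trend = trend, rh_mean = rh_mean, rh_amp = rh_amp, rh_sd = rh_sd,
              fraction_urban = fraction_urban,
              birth_start = as.integer(birth_start),
              birth_end = as.integer(birth_end),
              fraction_movers = fraction_movers,
              confounded_seasonality = isTRUE(confounded_seasonality))
  class(cfg) <- "world_config"
  cfg
}

#' Planted ("truth") parameters of the outcome process
#'
#' `alpha0` is the baseline neonatal mortality probability per birth (0.029,
#' i.e. 29 deaths per 1,000 births). `beta_heat` is the effect of one
#' deg C x day of cumulative heat (90th-percentile metric) on the per-1,000
#' mortality scale; the group multipliers scale it for births in the named
#' group (all 1 by default; set `mult_urban = 0` for a rural-only world, or
#' `mult_unimproved_water = 2` for a water-vulnerability world). Random
#' effects (s.d. on the probability scale) are drawn per cluster, per birth
#' year, and per (2-degree cell, calendar birth month). `gamma_checkups` is
#' the log-rate effect of one deg C x day on the Poisson prenatal-visit
#' count (non-positive).
#'
#' @param alpha0,beta_heat,gamma_checkups,mu0_visits Scalars (see above).
#' @param mult_rural,mult_urban,mult_unimproved_water,mult_unimproved_sanitation,mult_poor,mult_no_electricity,mult_low_edu
#'   Group multipliers on `beta_heat`.
#' @param sd_cluster,sd_year,sd_cellmonth Random-effect standard deviations.
#' @param b_male,b_birth_order,b_age,b_age_sq,b_edu Covariate coefficients on
#'   the probability scale (`b_age`, `b_age_sq` apply to mother age centered
#'   at 28).
#' @param b_urban Urban level shift (cluster-level, absorbed by cluster fixed
#'   effects; default reproduces a rural/urban mortality gap of ~2.5 per
#'   1,000).
#' @return A `truth_params` list.
#' @export
truth_params <- function(alpha0 = 0.029,
                         beta_heat = 0.03,
                         mult_rural = 1, mult_urban = 1,
                         mult_unimproved_water = 1,
                         mult_unimproved_sanitation = 1,
                         mult_poor = 1, mult_no_electricity = 1,
                         mult_low_edu = 1,
                         sd_cluster = 0.004, sd_year = 0.002,
                         sd_cellmonth = 0.003,
                         b_male = 0.003, b_birth_order = 0.001,
                         b_age = -2e-4, b_age_sq = 1e-5,
                         b_edu = -0.004, b_urban = -0.0025,
                         gamma_checkups = -0.0015, mu0_visits = 4) {
  stopifnot(gamma_checkups <= 0)
  tp <- as.list(environment())
  class(tp) <- "truth_params"
  tp
}

#' Generate the synthetic climate cube
#'
#' Daily dry-bulb temperature = latitude-dependent mean + seasonal sinusoid
#' (hemisphere-correct phase) + linear warming trend + AR(1) daily noise;
#' daily relative humidity = seasonal sinusoid (wet season opposite the hot
#' season) + noise, clipped to \[5, 99\]; monthly precipitation >= 0 with a
#' wet-season cycle. Fully reproducible from `config$seed`.
#'
#' @param config A [world_config()].
#' @param cells Optional `data.table(cell, lon, lat)` of pixel centers to
#'   simulate (defaults to every pixel in the box).
#' @return `list(daily = data.table(cell, date, t, rh), precip =
#'   data.table(cell, year, month, precip), cells)`.
#' @export
generate_climate <- function(config, cells = NULL) {
  stopifnot(inherits(config, "world_config"))
  step <- config$grid_step
  if (is.null(cells)) {
    lon <- seq(config$lon_range[1] + step / 2, config$lon_range[2], by = step)
    lat <- seq(config$lat_range[1] + step / 2, config$lat_range[2], by = step)
    cells <- data.table::CJ(lon = lon, lat = lat)
    cells[, cell := grid_cell_id(lon, lat, step)]
  }
  cells <- data.table::as.data.table(cells)[order(cell)]
  ncell <- nrow(cells)
  cal <- daily_calendar(config$years)
  nday <- nrow(cal)
  doy <- as.integer(format(cal$date, "%j"))
  yfrac <- cal$year + (doy - 0.5) / 365.25

  set.seed(config$seed * 11L + 2L)
  base <- 30 - 0.2 * abs(cells$lat) + stats::rnorm(ncell, 0, 1)
  peak <- ifelse(cells$lat < 0, 15, 196)  # hottest day-of-year by hemisphere
  seas <- config$seasonal_amp *
    cos(2 * pi * (outer(doy, peak, "-")) / 365.25)          # nday x ncell
  trend <- config$trend * (yfrac - min(config$years)) / 10

  innov <- matrix(stats::rnorm(nday * ncell, 0, config$noise_sd), nday, ncell)
  ar <- stats::filter(innov, filter = config$ar1, method = "recursive")
  tmat <- sweep(seas + as.matrix(ar), 2L, base, "+") + trend

  peak_rh <- ifelse(cells$lat < 0, 196, 15)  # wet season opposite the hot one
  rh_seas <- config$rh_amp * cos(2 * pi * (outer(doy, peak_rh, "-")) / 365.25)
  rhmat <- config$rh_mean + rh_seas +
    matrix(stats::rnorm(nday * ncell, 0, config$rh_sd), nday, ncell)
  rhmat <- pmin(99, pmax(5, rhmat))

  daily <- data.table::data.table(
    cell = rep(cells$cell, each = nday),
    date = rep(cal$date, times = ncell),
    t = as.numeric(tmat), rh = as.numeric(rhmat))

  months <- data.table::CJ(year = config$years, month = 1:12)
  nm <- nrow(months)
  wet <- 1 + 0.8 * cos(2 * pi * (outer(months$month * 30.4 - 15, peak_rh, "-")) / 365.25)
  pmat <- 80 * wet * matrix(exp(stats::rnorm(nm * ncell, 0, 0.4)), nm, ncell)
  precip <- data.table::data.table(
    cell = rep(cells$cell, each = nm),
    year = rep(months$year, times = ncell),
    month = rep(months$month, times = ncell),
    precip = as.numeric(pmat))

  list(daily = daily, precip = precip, cells = cells[])
}

#' Generate survey clusters and birth records (covariates only)
#'
#' Clusters are placed uniformly within country longitude strips, tagged
#' urban/rural, and keyed to their climate pixel and the nested 0.5/1/2-degree
#' cells. Births are assigned uniformly over the configured birth months;
#' covariates are drawn from simple documented marginals. Outcomes are
#' assigned separately by [assign_outcomes()].
#'
#' @param config A [world_config()].
#' @return `list(clusters, births)` of `data.table`s.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed * 11L + 1L)
  C <- config$n_countries * config$clusters_per_country
  strip <- diff(config$lon_range) / config$n_countries
  country <- rep(seq_len(config$n_countries), each = config$clusters_per_country)
  lon <- config$lon_range[1] + (country - 1) * strip + stats::runif(C) * strip
  lat <- config$lat_range[1] + stats::runif(C) * diff(config$lat_range)
  clusters <- data.table::data.table(
    cluster_id = seq_len(C), country = country, lon = lon, lat = lat,
    residence_type = ifelse(stats::runif(C) < config$fraction_urban, "urban", "rural"),
    cell = grid_cell_id(lon, lat, config$grid_step),
    pcell = grid_cell_id(lon, lat, 0.5),
    cell1 = grid_cell_id(lon, lat, 1),
    cell2 = grid_cell_id(lon, lat, 2))

  n <- C * config$births_per_cluster
  ym0 <- ym_index(config$birth_start[1], config$birth_start[2])
  ym1 <- ym_index(config$birth_end[1], config$birth_end[2])
  bym <- ym0 + sample.int(ym1 - ym0 + 1L, n, replace = TRUE) - 1L
  age <- pmin(49L, pmax(13L, as.integer(round(13 + 36 * stats::rbeta(n, 2.5, 3.5)))))
  births <- data.table::data.table(
    birth_id = seq_len(n),
    cluster_id = rep(clusters$cluster_id, each = config$births_per_cluster),
    birth_year = ym_year(bym), birth_month = ym_month(bym),
    gender = as.integer(stats::runif(n) < 0.512),            # 1 = male
    birth_order = 1L + stats::rpois(n, 1.5),
    mother_age = age,
    mother_edu = as.integer(stats::runif(n) < 0.35),         # 1 = secondary+
    wealth_q = sample.int(5L, n, replace = TRUE),
    water_class = ifelse(stats::runif(n) < 0.65, "improved", "unimproved"),
    sanitation_class = ifelse(stats::runif(n) < 0.4, "improved", "unimproved"))
  births[, mother_age_sq := mother_age^2]
  urb <- clusters$residence_type[births$cluster_id] == "urban"
  births[, electricity := as.integer(stats::runif(n) < stats::plogis(-1.2 + 2.2 * urb))]
  mover <- stats::runif(n) < config$fraction_movers
  births[, residence_duration := ifelse(mover, sample(0:3, n, replace = TRUE),
                                        sample(4:30, n, replace = TRUE))]
  births[, interview_ym := bym + sample.int(36L, n, replace = TRUE)]
  list(clusters = clusters[], births = births[])
}

#' Assign outcomes from the planted linear-probability process
#'
#' Death probability per birth: `alpha0 + (beta_heat * multiplier) *
#' cum_heat_90 / 1000 + cluster RE + birth-year RE + (2-degree cell x birth
#' month) RE + covariate terms`, clipped to \[0, 1\] (clip fraction reported;
#' warning above 5%, error above 50%). Deaths are Bernoulli draws; prenatal
#' visits are Poisson with log-rate `log(mu0) + gamma_checkups *
#' cum_heat_90`. Postnatal exposure has no planted effect.
#'
#' @param births Birth table from [generate_population()].
#' @param clusters Cluster table (for residence type and 2-degree cell).
#' @param exposures Exposure table from [compute_exposures()].
#' @param truth A [truth_params()].
#' @param seed Integer seed for the outcome draws.
#' @param confounded_seasonality See [world_config()].
#' @return The birth table with `neonatal_death`, `prenatal_visits` and the
#'   planted linear predictor `p_true` added; attributes `clip_fraction`.
#' @export
assign_outcomes <- function(births, clusters, exposures, truth, seed,
                            confounded_seasonality = FALSE) {
  stopifnot(inherits(truth, "truth_params"))
  b <- merge(births, clusters[, c("cluster_id", "residence_type", "cell2", "lat"), with = FALSE],
             by = "cluster_id")
  b <- merge(b, exposures[, c("birth_id", "cum_heat_90"), with = FALSE],
             by = "birth_id")
  if (nrow(b) < nrow(births)) {
    stop("exposures missing for some births; compute exposures first", call. = FALSE)
  }
  data.table::setkeyv(b, "birth_id")
  set.seed(seed)

  re_cl <- stats::rnorm(max(b$cluster_id), 0, truth$sd_cluster)
  yrs <- sort(unique(b$birth_year))
  re_yr <- stats::setNames(stats::rnorm(length(yrs), 0, truth$sd_year), yrs)
  cm_key <- paste(b$cell2, b$birth_month, sep = ":")
  ucm <- sort(unique(cm_key))
  if (confounded_seasonality) {
    # effects follow the hemisphere-correct seasonal heat cycle
    mth <- as.integer(sub(".*:", "", ucm))
    phase <- cos(2 * pi * (mth - 1) / 12)  # peaks in January (southern summer)
    re_cm <- stats::setNames(truth$sd_cellmonth * sqrt(2) * phase, ucm)
  } else {
    re_cm <- stats::setNames(stats::rnorm(length(ucm), 0, truth$sd_cellmonth), ucm)
  }

  mult <- ifelse(b$residence_type == "urban", truth$mult_urban, truth$mult_rural) *
    ifelse(b$water_class == "unimproved", truth$mult_unimproved_water, 1) *
    ifelse(b$sanitation_class == "unimproved", truth$mult_unimproved_sanitation, 1) *
    ifelse(b$wealth_q <= 3, truth$mult_poor, 1) *
    ifelse(b$electricity == 0L, truth$mult_no_electricity, 1) *
    ifelse(b$mother_edu == 0L, truth$mult_low_edu, 1)

  agec <- b$mother_age - 28
  p <- truth$alpha0 +
    (truth$beta_heat * mult) * b$cum_heat_90 / 1000 +
    re_cl[b$cluster_id] + re_yr[as.character(b$birth_year)] + re_cm[cm_key] +
    truth$b_male * b$gender + truth$b_birth_order * b$birth_order +
    truth$b_age * agec + truth$b_age_sq * agec^2 +
    truth$b_edu * b$mother_edu +
    truth$b_urban * (b$residence_type == "urban")
  clip_fraction <- mean(p < 0 | p > 1)
  if (clip_fraction > 0.5) stop("degenerate truth: over half of probabilities clipped", call. = FALSE)
  if (clip_fraction > 0.05) warning(sprintf("%.1f%% of probabilities clipped", 100 * clip_fraction))
  pc <- pmin(1, pmax(0, p))

  out <- data.table::copy(births)
  data.table::setkeyv(out, "birth_id")
  out[, p_true := pc]
  out[, neonatal_death := stats::rbinom(.N, 1L, pc)]
  out[, prenatal_visits := stats::rpois(.N, exp(log(truth$mu0_visits) +
        truth$gamma_checkups * b$cum_heat_90))]
  data.table::setattr(out, "clip_fraction", clip_fraction)
  out[]
}

#' Simulate a full synthetic study
#'
#' Orchestrates population, climate, wet-bulb conversion, thresholds,
#' exposures, outcomes, and the merged analysis table.
#'
#' @param config A [world_config()].
#' @param truth A [truth_params()].
#' @param k Reference window length in years for thresholds (default 3).
#' @param keep_climate Keep the daily climate/wet-bulb table in the result
#'   (default `FALSE`; it is the largest object).
#' @return `list(config, truth, clusters, births, thresholds, exposures,
#'   rejects, analysis, clip_fraction)`.
#' @export
simulate_world <- function(config = world_config(), truth = truth_params(),
                           k = 3L, keep_climate = FALSE) {
  pop <- generate_population(config)
  used <- unique(pop$clusters[, c("cell", "lon", "lat"), with = FALSE], by = "cell")
  used[, `:=`(lon = (floor(lon / config$grid_step) + 0.5) * config$grid_step,
              lat = (floor(lat / config$grid_step) + 0.5) * config$grid_step)]
  clim <- generate_climate(config, cells = used)
  wt <- climate_wetbulb(clim$daily)

  first_win_year <- ym_year(ym_index(config$birth_start[1], config$birth_start[2]) - 9L)
  target_years <- first_win_year:config$birth_end[1]
  thr <- build_thresholds(wt, target_years, k = k)

  expo <- compute_exposures(pop$births, pop$clusters, wt, thr, clim$precip)
  births <- assign_outcomes(pop$births, pop$clusters, expo$exposures, truth,
                            seed = config$seed * 11L + 3L,
                            confounded_seasonality = config$confounded_seasonality)
  analysis <- merge_tables(births, expo$exposures, pop$clusters)
  res <- list(config = config, truth = truth, clusters = pop$clusters,
              births = births, thresholds = thr, exposures = expo$exposures,
              rejects = expo$rejects, analysis = analysis,
              clip_fraction = attr(births, "clip_fraction"))
  if (keep_climate) { res$climate <- clim; res$wetbulb <- wt }
  res
}
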