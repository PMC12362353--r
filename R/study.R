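# The study regression battery: baseline, rural/urban split, mechanism,
# subgroup heterogeneity, and robustness variants. Every run is a separate
# absorbed-FE linear probability model; results are returned as one tidy
# table (one row per exposure regressor per model) plus the full fit objects.

#' Default individual-level controls of the baseline model
#'
#' Infant gender and birth order; mother's age at birth, its square, and her
#' education tier; window-mean precipitation.
#' @return Character vector of column names.
#' @export
default_controls <- function() {
  c("gender", "birth_order", "mother_age", "mother_age_sq", "mother_edu",
    "mean_precip")
}

#' Fixed-effect scheme variants
#'
#' `"cell2_month"` (default): DHS cluster; birth year; 2-degree cell x birth
#' month. `"country_month"` and `"cell1_month"` swap the third factor for
#' country x birth month or 1-degree cell x birth month.
#' @param variant Scheme name.
#' @return List of factor definitions for [fe_spec()].
#' @export
fe_scheme <- function(variant = c("cell2_month", "country_month", "cell1_month",
                                  "cluster_year")) {
  variant <- match.arg(variant)
  third <- switch(variant,
                  cell2_month = c("cell2", "birth_month"),
                  country_month = c("country", "birth_month"),
                  cell1_month = c("cell1", "birth_month"),
                  cluster_year = NULL)
  c(list("cluster_id", "birth_year"), if (!is.null(third)) list(third))
}

tidy_fit <- function(fit, terms = NULL, analysis = NA_character_,
                     stratum = NA_character_, metric = NA_character_,
                     percentile = NA_integer_, side = NA_character_,
                     outcome_mean = NA_real_) {
  tab <- fit$table
  if (!is.null(terms)) tab <- tab[tab$term %in% terms]
  cbind(data.table::data.table(analysis = analysis, stratum = stratum,
                               metric = metric, percentile = percentile,
                               side = side),
        tab,
        data.table::data.table(n = fit$n, n_clusters = fit$n_clusters,
                               outcome_mean = outcome_mean))
}

#' Run a battery of exposure regressions
#'
#' One regression per (metric, percentile): the outcome on that single
#' exposure metric plus controls, with absorbed fixed effects and
#' cluster-robust standard errors.
#'
#' @param data Merged analysis table ([merge_tables()] output).
#' @param analysis Analysis id recorded in the tidy output.
#' @param metrics `"cumulative"`, `"days"`, or both (default).
#' @param percentiles Percentile set (default heat 75/85/90/95).
#' @param side `"heat"` or `"cold"`.
#' @param outcome Outcome column (default `"neonatal_death"`, scaled x1000).
#' @param controls Control columns (default [default_controls()]).
#' @param fe Fixed-effect scheme (default `fe_scheme("cell2_month")`).
#' @param filter Optional filter expression (quoted) applied per regression.
#' @param stratum Stratum label for the tidy output.
#' @param add_postnatal Also include the matching postnatal metric as a
#'   second regressor (robustness variant).
#' @param scale_outcome Multiply outcome by 1000 (default `TRUE`).
#' @return `list(results = tidy data.table, fits = named list of fe_fit)`.
#' @export
run_battery <- function(data, analysis = "baseline",
                        metrics = c("cumulative", "days"),
                        percentiles = HEAT_PERCENTILES,
                        side = "heat",
                        outcome = "neonatal_death",
                        controls = default_controls(),
                        fe = fe_scheme("cell2_month"),
                        filter = NULL, stratum = NA_character_,
                        add_postnatal = FALSE, scale_outcome = TRUE) {
  out <- list(); fits <- list()
  om <- if (outcome %in% names(data)) {
    v <- data[[outcome]]
    if (!is.null(filter)) {
      keep <- eval(if (inherits(filter, "formula")) filter[[2]] else filter,
                   envir = data, enclos = parent.frame())
      v <- v[keep & !is.na(keep)]
    }
    mean(v) * (if (scale_outcome) 1000 else 1)
  } else NA_real_
  for (metric in metrics) {
    for (p in percentiles) {
      xcol <- metric_col(metric, p, side)
      regs <- xcol
      if (add_postnatal) regs <- c(regs, metric_col(metric, p, side, postnatal = TRUE))
      spec <- fe_spec(outcome, regs, controls, fe = fe,
                      scale_outcome = scale_outcome, filter = filter)
      fit <- fit_fe_lpm(spec, data)
      id <- paste(analysis, metric, p, sep = "_")
      fits[[id]] <- fit
      out[[id]] <- tidy_fit(fit, terms = regs, analysis = analysis,
                            stratum = stratum, metric = metric,
                            percentile = p, side = side, outcome_mean = om)
    }
  }
  list(results = data.table::rbindlist(out), fits = fits)
}

#' Baseline battery: 8 heat regressions
#'
#' Cumulative heat and heat days at the 75/85/90/95th percentiles, with the
#' default controls and fixed effects.
#' @inheritParams run_battery
#' @param ... Passed to [run_battery()].
#' @export
run_baseline <- function(data, ...) {
  run_battery(data, analysis = "baseline", ...)
}

#' Rural/urban split
#'
#' Runs the baseline battery separately on the rural and urban subsamples and
#' reports each subsample's neonatal mortality per 1,000 alongside.
#' @inheritParams run_battery
#' @param ... Passed to [run_battery()].
#' @export
run_residence_split <- function(data, ...) {
  res <- list()
  for (g in c("rural", "urban")) {
    if (!any(data$residence_type == g)) {
      stop("empty residence stratum: ", g, call. = FALSE)
    }
    res[[g]] <- run_battery(data, analysis = paste0("residence_", g),
                            filter = bquote(residence_type == .(g)),
                            stratum = g, ...)
  }
  list(results = data.table::rbindlist(lapply(res, `[[`, "results")),
       fits = c(res$rural$fits, res$urban$fits),
       outcome_means = vapply(res, function(r) r$results$outcome_mean[1], 0))
}

#' Prenatal-checkups mechanism battery
#'
#' Regresses the number of prenatal visits on each exposure metric with the
#' baseline controls minus infant gender (unknown during pregnancy) and the
#' same fixed effects. The outcome is a count, not scaled.
#' @inheritParams run_battery
#' @param ... Passed to [run_battery()].
#' @export
run_checkups_mechanism <- function(data, ...) {
  run_battery(data, analysis = "checkups", outcome = "prenatal_visits",
              controls = setdiff(default_controls(), "gender"),
              scale_outcome = FALSE, ...)
}

#' Two-level grouping rules for heterogeneity axes
#'
#' Wealth quintiles 1-3 ("poorest, poorer, middle") versus 4-5 ("richer,
#' richest"); education none/primary versus secondary/higher; electricity,
#' water and sanitation as recorded.
#' @param data Analysis table.
#' @param axis One of `"water"`, `"sanitation"`, `"wealth"`, `"electricity"`,
#'   `"education"`.
#' @return Character vector of stratum labels (two levels), aligned to rows.
#' @export
subgroup_labels <- function(data, axis = c("water", "sanitation", "wealth",
                                           "electricity", "education")) {
  axis <- match.arg(axis)
  switch(axis,
    water = data$water_class,
    sanitation = data$sanitation_class,
    wealth = ifelse(data$wealth_q <= 3L, "poor_middle", "richer_richest"),
    electricity = ifelse(data$electricity == 1L, "electricity", "no_electricity"),
    education = ifelse(data$mother_edu == 1L, "secondary_higher", "none_primary"))
}

#' Subgroup heterogeneity: split fits plus a stacked interaction
#'
#' Runs the battery within each stratum of the axis, and additionally fits a
#' stacked model with an exposure-by-stratum interaction so the between-strata
#' difference carries a standard error.
#'
#' @inheritParams run_battery
#' @param axis See [subgroup_labels()].
#' @param ... Passed to [run_battery()].
#' @return `list(results, fits, interaction)`; `interaction` is a tidy table
#'   of the interaction (delta) coefficients.
#' @export
run_subgroup <- function(data, axis, metrics = c("cumulative", "days"),
                         percentiles = HEAT_PERCENTILES, ...) {
  labs <- subgroup_labels(data, axis)
  lv <- sort(unique(labs))
  if (length(lv) != 2L) stop("axis does not split the sample in two strata", call. = FALSE)
  dt <- data.table::copy(data.table::as.data.table(data))
  dt[, .stratum := labs]
  controls <- default_controls()
  if (axis == "education") controls <- setdiff(controls, "mother_edu")

  res <- list()
  for (g in lv) {
    if (!any(labs == g)) stop("empty stratum: ", g, call. = FALSE)
    res[[g]] <- run_battery(dt, analysis = paste0(axis, "_", g),
                            metrics = metrics, percentiles = percentiles,
                            filter = bquote(.stratum == .(g)),
                            stratum = g, controls = controls, ...)
  }

  inter <- list()
  dt[, .g2 := as.numeric(.stratum == lv[2])]
  for (metric in metrics) {
    for (p in percentiles) {
      xcol <- metric_col(metric, p, "heat")
      dt[, .x_g2 := get(xcol) * .g2]
      spec <- fe_spec("neonatal_death", c(xcol, ".x_g2"),
                      c(controls, ".g2"), scale_outcome = TRUE, ...)
      fit <- fit_fe_lpm(spec, dt)
      inter[[paste(metric, p)]] <- tidy_fit(
        fit, terms = ".x_g2", analysis = paste0(axis, "_interaction"),
        stratum = paste(lv[2], "minus", lv[1]), metric = metric,
        percentile = p, side = "heat")
    }
  }
  list(results = data.table::rbindlist(lapply(res, `[[`, "results")),
       fits = do.call(c, lapply(res, `[[`, "fits")),
       interaction = data.table::rbindlist(inter))
}

#' Robustness variants
#'
#' - `"migration"`: keep births whose mother's residence duration covers
#'   conception through the interview (duration in integer years, converted
#'   at 12 months/year, inclusive).
#' - `"postnatal"`: add the matching birth-month exposure as a second
#'   regressor in every model.
#' - `"cold"`: swap in the 8 cold metrics (strict shortfall below the
#'   25/15/10/5th percentiles).
#' - `"fe_country_month"`, `"fe_cell1_month"`: alternative fixed-effect
#'   schemes.
#' - `"exclude_country"`: drop one country (`exclude`).
#'
#' @inheritParams run_battery
#' @param variant Variant name.
#' @param exclude Country id(s) dropped for `"exclude_country"`.
#' @param ... Passed to [run_battery()].
#' @return As [run_battery()]; filter variants also carry `n_kept`/`n_dropped`.
#' @export
run_robustness <- function(data, variant = c("migration", "postnatal", "cold",
                                             "fe_country_month", "fe_cell1_month",
                                             "exclude_country"),
                           exclude = NULL, ...) {
  variant <- match.arg(variant)
  dt <- data.table::as.data.table(data)
  if (variant == "migration") {
    need_months <- dt$interview_ym - ym_index(dt$birth_year, dt$birth_month) + 9L
    keep <- dt$residence_duration * 12L >= need_months
    out <- run_battery(dt[keep], analysis = "migration", ...)
    out$n_kept <- sum(keep); out$n_dropped <- sum(!keep)
    return(out)
  }
  if (variant == "postnatal") {
    return(run_battery(dt, analysis = "postnatal", add_postnatal = TRUE, ...))
  }
  if (variant == "cold") {
    args <- list(...)
    if (!"percentiles" %in% names(args)) args$percentiles <- COLD_PERCENTILES
    return(do.call(run_battery,
                   c(list(dt, analysis = "cold_placebo", side = "cold"), args)))
  }
  if (variant == "fe_country_month") {
    return(run_battery(dt, analysis = "fe_country_month",
                       fe = fe_scheme("country_month"), ...))
  }
  if (variant == "fe_cell1_month") {
    return(run_battery(dt, analysis = "fe_cell1_month",
                       fe = fe_scheme("cell1_month"), ...))
  }
  if (is.null(exclude)) stop("`exclude` required for exclude_country", call. = FALSE)
  keep <- !(dt$country %in% exclude)
  out <- run_battery(dt[keep], analysis = "exclude_country", ...)
  out$n_kept <- sum(keep); out$n_dropped <- sum(!keep)
  out
}

#' Reference-window variant: recompute exposures under a different window
#'
#' Rebuilds thresholds from the same climate under window length `k` (rolling
#' `t-k ... t-1`; `reference = "fixed"` pools a fixed climatology instead),
#' recomputes exposures, restricts births to those whose window the new
#' reference can cover, and reruns the baseline battery.
#'
#' @param world A [simulate_world()] result with `keep_climate = TRUE`.
#' @param k Window length in years.
#' @param reference `"rolling"` or `"fixed"` (see [build_thresholds()]).
#' @param ... Passed to [run_battery()].
#' @export
run_window_variant <- function(world, k, reference = "rolling", ...) {
  if (is.null(world$wetbulb)) stop("world must be simulated with keep_climate = TRUE", call. = FALSE)
  cfg <- world$config
  if (reference == "rolling") {
    first_target <- min(cfg$years) + k
    target_years <- first_target:cfg$birth_end[1]
    thr <- build_thresholds(world$wetbulb, target_years, k = k)
    # window months must fall in covered target years: birth month >= Oct of first_target
    min_bym <- ym_index(first_target, 1L) + 9L
  } else {
    first_win_year <- ym_year(ym_index(cfg$birth_start[1], cfg$birth_start[2]) - 9L)
    thr <- build_thresholds(world$wetbulb, first_win_year:cfg$birth_end[1],
                            k = k, reference = "fixed", ref_years = cfg$years)
    min_bym <- ym_index(cfg$birth_start[1], cfg$birth_start[2])
  }
  births <- world$births
  expo <- compute_exposures(births, world$clusters, world$wetbulb, thr,
                            world$climate$precip)
  analysis <- merge_tables(births[ym_index(birth_year, birth_month) >= min_bym],
                           expo$exposures, world$clusters)
  run_battery(analysis, analysis = paste0("window_k", k,
                                          if (reference == "fixed") "_fixed" else ""),
              ...)
}

#' Run a configured study plan
#'
#' Executes a named list of analyses over one analysis table and returns the
#' stacked tidy results plus a manifest-style log of filters and counts.
#' The default plan is the full battery: baseline, residence split, checkups
#' mechanism, the five heterogeneity axes, and the data-level robustness
#' variants.
#'
#' @param data Merged analysis table.
#' @param plan Character vector of analysis names (subset of the default).
#' @param exclude Country id(s) for the exclude-country variant.
#' @return `list(results, log)`.
#' @export
run_study <- function(data,
                      plan = c("baseline", "residence", "checkups",
                               "water", "sanitation", "wealth", "electricity",
                               "education", "migration", "postnatal", "cold",
                               "fe_country_month", "fe_cell1_month"),
                      exclude = NULL) {
  res <- list(); log <- list()
  for (a in plan) {
    r <- switch(a,
      baseline = run_baseline(data),
      residence = run_residence_split(data),
      checkups = run_checkups_mechanism(data),
      water = , sanitation = , wealth = , electricity = , education =
        run_subgroup(data, axis = a),
      migration = , postnatal = , cold = , fe_country_month = ,
      fe_cell1_month = run_robustness(data, variant = a),
      exclude_country = run_robustness(data, variant = a, exclude = exclude),
      stop("unknown analysis: ", a, call. = FALSE))
    res[[a]] <- r$results
    if (!is.null(r$interaction)) res[[paste0(a, "_interaction")]] <- r$interaction
    log[[a]] <- list(n_models = nrow(r$results),
                     n_kept = r$n_kept, n_dropped = r$n_dropped)
  }
  list(results = data.table::rbindlist(res, fill = TRUE), log = log)
}
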