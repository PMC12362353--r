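# Gestational and postnatal heat/cold exposure metrics.
#
# A day is extreme under strict inequality: wet-bulb strictly above the heat
# cutoff, or strictly below the cold cutoff; a day exactly at the cutoff
# contributes nothing to either margin. Each day is compared against the
# cutoff of its own (location, season, calendar year) — windows spanning a
# year boundary therefore mix threshold vintages.

#' Derive the daily wet-bulb series from a climate table
#'
#' @param climate A `data.table` with columns `cell`, `date` (Date), `t`
#'   (dry-bulb deg C) and `rh` (percent).
#' @return The same table with `year`, `month`, `season`, `ym` and `wt`
#'   (wet-bulb deg C) columns added; out-of-envelope input count is attached
#'   as attribute `n_out_of_envelope`.
#' @export
climate_wetbulb <- function(climate) {
  stopifnot(data.table::is.data.table(climate),
            all(c("cell", "date", "t", "rh") %in% names(climate)))
  out <- data.table::copy(climate)
  ud <- sort(unique(out$date))          # format once per unique day, not per row
  uy <- as.integer(format(ud, "%Y"))
  um <- as.integer(format(ud, "%m"))
  ix <- match(as.numeric(out$date), as.numeric(ud))
  yr <- uy[ix]
  mo <- um[ix]
  out[, `:=`(year = yr, month = mo, season = season_of_month(mo),
             ym = ym_index(yr, mo))]
  out[, wt := stull_wet_bulb(t, rh)]
  data.table::setattr(out, "n_out_of_envelope", stull_envelope_flags(out$t, out$rh))
  out[]
}

#' Cumulative exceedance over a window of days
#'
#' Intensive-margin degree-day metric: for heat, the sum of `wt - cutoff` over
#' days strictly above the cutoff; for cold, the sum of `cutoff - wt` over
#' days strictly below it. Always nonnegative, in deg C x day.
#'
#' @param daily_wt Numeric vector of daily wet-bulb values (deg C).
#' @param cutoffs Numeric vector, one threshold per day (each day's own
#'   location/season/year cutoff).
#' @param side `"heat"` or `"cold"`.
#' @return A single nonnegative number (deg C x day).
#' @export
cumulative_exceedance <- function(daily_wt, cutoffs, side = c("heat", "cold")) {
  side <- match.arg(side)
  if (length(daily_wt) != length(cutoffs)) {
    stop("`daily_wt` and `cutoffs` must have the same length", call. = FALSE)
  }
  if (side == "heat") sum(pmax(0, daily_wt - cutoffs)) else sum(pmax(0, cutoffs - daily_wt))
}

#' Count of extreme days over a window
#'
#' Extensive-margin metric: days strictly above (heat) or strictly below
#' (cold) the day's cutoff.
#'
#' @inheritParams cumulative_exceedance
#' @return Integer count in `[0, length(daily_wt)]`.
#' @export
exceedance_days <- function(daily_wt, cutoffs, side = c("heat", "cold")) {
  side <- match.arg(side)
  if (length(daily_wt) != length(cutoffs)) {
    stop("`daily_wt` and `cutoffs` must have the same length", call. = FALSE)
  }
  if (side == "heat") sum(daily_wt > cutoffs) else sum(daily_wt < cutoffs)
}

# Exposure metric column name, e.g. cum_heat_75, heat_days_90, cum_cold_25.
#' @export
metric_col <- function(metric = c("cumulative", "days"), percentile,
                       side = c("heat", "cold"), postnatal = FALSE) {
  metric <- match.arg(metric)
  side <- match.arg(side)
  base <- if (metric == "cumulative") paste0("cum_", side, "_", percentile)
          else paste0(side, "_days_", percentile)
  if (postnatal) paste0("post_", base) else base
}

# Monthly aggregation of per-day exceedances: exact for whole-calendar-month
# windows because both margins are additive over days and every day's cutoff
# depends only on its own (cell, season, year).
monthly_exposure <- function(wt, thresholds) {
  stopifnot(all(c("cell", "year", "season", "ym", "wt") %in% names(wt)))
  thr_wide <- data.table::dcast(thresholds, cell + season + year ~ percentile,
                                value.var = "cutoff")
  pcols <- setdiff(names(thr_wide), c("cell", "season", "year"))
  d <- merge(wt[, c("cell", "year", "season", "ym", "wt"), with = FALSE],
             thr_wide, by = c("cell", "season", "year"), all.x = TRUE)
  miss <- is.na(d[[pcols[1]]])
  if (any(miss)) d <- d[!miss]
  for (p in HEAT_PERCENTILES) {
    cut <- d[[as.character(p)]]
    d[, (metric_col("cumulative", p, "heat")) := pmax(0, wt - cut)]
    d[, (metric_col("days", p, "heat")) := as.integer(wt > cut)]
  }
  for (p in COLD_PERCENTILES) {
    cut <- d[[as.character(p)]]
    d[, (metric_col("cumulative", p, "cold")) := pmax(0, cut - wt)]
    d[, (metric_col("days", p, "cold")) := as.integer(wt < cut)]
  }
  mcols <- c(sapply(HEAT_PERCENTILES, function(p) metric_col("cumulative", p, "heat")),
             sapply(HEAT_PERCENTILES, function(p) metric_col("days", p, "heat")),
             sapply(COLD_PERCENTILES, function(p) metric_col("cumulative", p, "cold")),
             sapply(COLD_PERCENTILES, function(p) metric_col("days", p, "cold")))
  out <- d[, c(list(n_days = .N), lapply(.SD, sum)),
           by = c("cell", "ym"), .SDcols = mcols]
  data.table::setkeyv(out, c("cell", "ym"))
  out
}

# Number of days in calendar month of ym index.
days_in_ym <- function(ym) {
  y <- ym_year(ym); m <- ym_month(ym)
  first <- as.Date(sprintf("%04d-%02d-01", y, m))
  nxt <- as.Date(sprintf("%04d-%02d-01", y + (m == 12L), m %% 12L + 1L))
  as.integer(nxt - first)
}

#' Postnatal (birth-month) exposure metrics for one location
#'
#' Computes the cumulative-exceedance and day-count metrics over calendar
#' month `m` only (the month of birth), for all heat and cold percentiles.
#'
#' @param birth_year,birth_month The birth month m.
#' @param wt Daily wet-bulb `data.table` for one cell (columns `cell`, `year`,
#'   `season`, `ym`, `wt`).
#' @param thresholds A threshold table from [build_thresholds()].
#' @return One-row `data.table` of the 16 metrics (names as [metric_col()]).
#' @export
postnatal_exposure <- function(birth_year, birth_month, wt, thresholds) {
  bym <- ym_index(birth_year, birth_month)
  sel <- which(wt[["ym"]] == bym)
  mo <- monthly_exposure(wt[sel], thresholds)
  if (nrow(mo) != 1L || mo$n_days != days_in_ym(bym)) {
    stop(sprintf("birth month %d-%02d not fully covered by climate data",
                 birth_year, birth_month), call. = FALSE)
  }
  mo[, c("cell", "ym", "n_days") := NULL]
  mo[]
}

#' Mean monthly precipitation over the gestational window
#'
#' Arithmetic mean of the 9 monthly precipitation values (mm/month) for the
#' months m-9 ... m-1 at one precipitation cell.
#'
#' @param birth_year,birth_month The birth month m.
#' @param precip `data.table` with columns `year`, `month`, `precip` for one
#'   cell (an optional `cell` column is ignored; it must be single-valued).
#' @return Mean precipitation in mm/month.
#' @export
mean_precipitation <- function(birth_year, birth_month, precip) {
  if ("cell" %in% names(precip) && length(unique(precip$cell)) > 1L) {
    stop("`precip` must contain a single cell series", call. = FALSE)
  }
  win <- gestational_window(birth_year, birth_month)
  p <- merge(win, precip, by = c("year", "month"))
  if (nrow(p) != 9L) {
    stop(sprintf("precipitation missing for %d of 9 window months",
                 9L - nrow(p)), call. = FALSE)
  }
  mean(p$precip)
}

#' Compute gestational exposure records for a table of births
#'
#' For every birth, sums the per-day heat/cold exceedances and day counts over
#' the 9 calendar months m-9 ... m-1 (and, optionally, the birth month for
#' postnatal controls), plus the window-mean precipitation. Births whose
#' window is not fully covered by the climate or precipitation series are
#' returned in a rejects table with a reason, never silently dropped.
#'
#' @param births `data.table` with `birth_id`, `cluster_id`, `birth_year`,
#'   `birth_month`.
#' @param clusters `data.table` with `cluster_id`, `cell` (climate cell) and
#'   `pcell` (precipitation cell).
#' @param wt Daily wet-bulb table ([climate_wetbulb()] output) covering the
#'   needed cells and months.
#' @param thresholds Threshold table from [build_thresholds()].
#' @param precip `data.table` (`cell`, `year`, `month`, `precip`), cells keyed
#'   as `clusters$pcell`.
#' @param postnatal If `TRUE` (default) also compute birth-month metrics.
#' @return `list(exposures = <one row per covered birth>, rejects = <birth_id,
#'   reason>, meta = <k, estimator, inequality convention>)`.
#' @export
compute_exposures <- function(births, clusters, wt, thresholds, precip,
                              postnatal = TRUE) {
  stopifnot(all(c("birth_id", "cluster_id", "birth_year", "birth_month") %in% names(births)),
            all(c("cluster_id", "cell", "pcell") %in% names(clusters)))
  mo <- monthly_exposure(wt, thresholds)
  mo[, complete := n_days == days_in_ym(ym)]
  mcols <- setdiff(names(mo), c("cell", "ym", "n_days", "complete"))

  b <- merge(births[, c("birth_id", "cluster_id", "birth_year", "birth_month"), with = FALSE],
             clusters[, c("cluster_id", "cell", "pcell"), with = FALSE],
             by = "cluster_id", all.x = TRUE)
  no_cluster <- b[is.na(cell)]
  b <- b[!is.na(cell)]
  b[, bym := ym_index(birth_year, birth_month)]

  # expand to the 9 window months and join monthly aggregates
  win <- b[rep(seq_len(.N), each = 9L),
           c("birth_id", "cell", "bym"), with = FALSE]
  win[, wym := bym - rep(9:1, times = nrow(b))]
  win <- merge(win, mo, by.x = c("cell", "wym"), by.y = c("cell", "ym"),
               all.x = TRUE)
  cov <- win[, .(n_ok = sum(!is.na(n_days) & complete)), by = "birth_id"]
  covered_ids <- cov[n_ok == 9L, birth_id]
  expo <- win[birth_id %in% covered_ids,
              lapply(.SD, sum), by = "birth_id", .SDcols = mcols]
  for (col in grep("_days_", mcols, value = TRUE)) {
    data.table::set(expo, j = col, value = as.integer(expo[[col]]))
  }

  # window-mean precipitation
  pw <- b[rep(seq_len(.N), each = 9L), c("birth_id", "pcell", "bym"), with = FALSE]
  pw[, wym := bym - rep(9:1, times = nrow(b))]
  pr <- data.table::copy(precip)
  pr[, wym := ym_index(year, month)]
  pw <- merge(pw, pr[, c("cell", "wym", "precip"), with = FALSE],
              by.x = c("pcell", "wym"), by.y = c("cell", "wym"), all.x = TRUE)
  pm <- pw[, .(n_ok = sum(!is.na(precip)), mean_precip = mean(precip)), by = "birth_id"]

  expo <- merge(expo, pm[n_ok == 9L, c("birth_id", "mean_precip"), with = FALSE],
                by = "birth_id", all.x = TRUE)

  post_missing <- integer(0)
  if (postnatal) {
    post <- merge(b[, c("birth_id", "cell", "bym"), with = FALSE], mo,
                  by.x = c("cell", "bym"), by.y = c("cell", "ym"), all.x = TRUE)
    post_ok <- post[!is.na(n_days) & complete == TRUE, c("birth_id", mcols), with = FALSE]
    post_missing <- setdiff(covered_ids, post_ok$birth_id)
    data.table::setnames(post_ok, mcols, paste0("post_", mcols))
    expo <- merge(expo, post_ok, by = "birth_id", all.x = TRUE)
  }

  # rejects: anything without a full record
  reasons <- data.table::rbindlist(list(
    data.table::data.table(birth_id = no_cluster$birth_id, reason = "unknown cluster"),
    data.table::data.table(birth_id = cov[n_ok < 9L, birth_id], reason = "window not covered"),
    data.table::data.table(birth_id = pm[n_ok < 9L, birth_id], reason = "precipitation not covered"),
    data.table::data.table(birth_id = post_missing, reason = "birth month not covered")
  ))
  reasons <- unique(reasons, by = "birth_id")
  expo <- expo[stats::complete.cases(expo)]
  data.table::setkeyv(expo, "birth_id")
  list(exposures = expo[],
       rejects = reasons[],
       meta = list(k = attr(thresholds, "k"),
                   estimator = attr(thresholds, "estimator"),
                   inequality = "strict",
                   window_months = 9L))
}
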