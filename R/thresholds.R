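# Location-specific seasonal percentile thresholds from rolling reference windows.

#' Study percentile sets
#'
#' Heat thresholds use the 75/85/90/95th percentiles, cold the 25/15/10/5th;
#' `ALL_PERCENTILES` is their union, the default set for threshold tables.
#' @export
HEAT_PERCENTILES <- c(75L, 85L, 90L, 95L)

#' @rdname HEAT_PERCENTILES
#' @export
COLD_PERCENTILES <- c(25L, 15L, 10L, 5L)

#' @rdname HEAT_PERCENTILES
#' @export
ALL_PERCENTILES <- c(5L, 10L, 15L, 25L, 75L, 85L, 90L, 95L)

#' Build seasonal percentile thresholds from a rolling reference window
#'
#' For each location, season `s` and target year `t`, the cutoff at percentile
#' `p` is the `p`-th percentile of all daily wet-bulb values at that location
#' whose (season, year) label is (`s`, `y`) for `y` in `t-k ... t-1`, pooled
#' across the whole window (about `k * 90` days). Percentiles use sorted-order
#' linear interpolation (`stats::quantile` type 7). With
#' `reference = "fixed"`, the pooled window is `ref_years` for every target
#' year instead of rolling — used for long-climatology variants where a rolling
#' window would need data before the record starts.
#'
#' @param wt A `data.table` of daily wet-bulb values with columns `cell`
#'   (location id), `year`, `season` (1-4) and `wt` (deg C). Extra columns are
#'   ignored. Helper [climate_wetbulb()] produces this from a climate table.
#' @param target_years Integer vector of years for which thresholds are needed.
#' @param k Reference window length in years (default 3).
#' @param percentiles Integer percentiles to compute (default the study set
#'   5, 10, 15, 25, 75, 85, 90, 95).
#' @param reference `"rolling"` (default; window `t-k ... t-1`) or `"fixed"`
#'   (window `ref_years` for all targets).
#' @param ref_years Years of the fixed reference window when
#'   `reference = "fixed"`.
#' @return A `data.table` (cell, season, year, percentile, cutoff) with
#'   attributes `k`, `estimator` ("type7_linear_interpolation") and
#'   `reference`.
#' @export
build_thresholds <- function(wt, target_years, k = 3L,
                             percentiles = ALL_PERCENTILES,
                             reference = c("rolling", "fixed"),
                             ref_years = NULL) {
  reference <- match.arg(reference)
  stopifnot(data.table::is.data.table(wt),
            all(c("cell", "year", "season", "wt") %in% names(wt)))
  target_years <- sort(unique(as.integer(target_years)))
  percentiles <- sort(as.integer(percentiles))
  k <- as.integer(k)
  have_years <- sort(unique(wt$year))

  if (reference == "rolling") {
    for (ty in target_years) {
      need <- (ty - k):(ty - 1L)
      if (!all(need %in% have_years)) {
        stop(sprintf(
          "insufficient reference years for target year %d (need %d-%d, first gap at season 1)",
          ty, ty - k, ty - 1L), call. = FALSE)
      }
    }
  } else {
    if (is.null(ref_years)) stop("`ref_years` required for fixed reference", call. = FALSE)
    if (!all(ref_years %in% have_years)) {
      stop("fixed reference years not covered by the wet-bulb series", call. = FALSE)
    }
  }

  probs <- percentiles / 100
  qfun <- function(x) as.list(stats::quantile(x, probs = probs, type = 7, names = FALSE))

  out <- vector("list", length(target_years))
  if (reference == "fixed") {
    idx <- wt[["year"]] %in% ref_years
    base <- wt[idx, qfun(wt), by = c("cell", "season")]
    for (i in seq_along(target_years)) {
      b <- data.table::copy(base)
      b[, year := target_years[i]]
      out[[i]] <- b
    }
  } else {
    for (i in seq_along(target_years)) {
      ty <- target_years[i]
      idx <- wt[["year"]] >= (ty - k) & wt[["year"]] <= (ty - 1L)
      ref <- wt[idx]
      th <- ref[, qfun(wt), by = c("cell", "season")]
      th[, year := ty]
      out[[i]] <- th
    }
  }
  thr <- data.table::rbindlist(out)
  data.table::setnames(thr, c("cell", "season",
                              paste0("V", seq_along(percentiles)), "year"))
  thr <- data.table::melt(thr, id.vars = c("cell", "season", "year"),
                          variable.name = "pidx", value.name = "cutoff")
  thr[, percentile := percentiles[as.integer(pidx)]]
  thr[, pidx := NULL]
  data.table::setcolorder(thr, c("cell", "season", "year", "percentile", "cutoff"))
  data.table::setkeyv(thr, c("cell", "season", "year", "percentile"))
  data.table::setattr(thr, "k", k)
  data.table::setattr(thr, "estimator", "type7_linear_interpolation")
  data.table::setattr(thr, "reference", reference)
  thr[]
}
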