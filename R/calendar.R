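# Calendar helpers: seasons, month indexing, gestational windows.
#
# Months are frequently carried as a single integer index ym = 12*year + (month-1)
# so that month arithmetic is plain integer arithmetic.

#' Month index helpers
#'
#' `ym_index()` maps a (year, month) pair to the integer `12*year + (month-1)`;
#' `ym_year()` and `ym_month()` invert it. Useful for windowed month arithmetic
#' (gestational windows, interview lags) without date objects.
#'
#' @param year,month Integer vectors.
#' @param ym Integer month index.
#' @return Integer vector.
#' @export
ym_index <- function(year, month) {
  stopifnot(all(month >= 1L), all(month <= 12L))
  as.integer(12L * year + (month - 1L))
}

#' @rdname ym_index
#' @export
ym_year <- function(ym) as.integer(ym %/% 12L)

#' @rdname ym_index
#' @export
ym_month <- function(ym) as.integer(ym %% 12L + 1L)

#' Assign calendar quarters as seasons
#'
#' Seasons are calendar quarters: season 1 = Jan-Mar, 2 = Apr-Jun,
#' 3 = Jul-Sep, 4 = Oct-Dec. Thresholds are computed per (location, season,
#' year), so each day carries the season of its month and its calendar year.
#'
#' @param dates A `Date` vector, or `NULL` if `year`/`month` are given.
#' @param year,month Alternative integer specification.
#' @return A `data.table` with columns `season` (1-4) and `year`.
#' @export
assign_seasons <- function(dates = NULL, year = NULL, month = NULL) {
  if (!is.null(dates)) {
    if (!inherits(dates, "Date")) stop("`dates` must be a Date vector", call. = FALSE)
    year <- as.integer(format(dates, "%Y"))
    month <- as.integer(format(dates, "%m"))
  }
  stopifnot(length(year) == length(month))
  data.table::data.table(season = season_of_month(month), year = as.integer(year))
}

#' @rdname assign_seasons
#' @export
season_of_month <- function(month) {
  month <- as.integer(month)
  stopifnot(all(month >= 1L & month <= 12L))
  (month - 1L) %/% 3L + 1L
}

#' Gestational window of a birth month
#'
#' Returns the 9 full calendar months strictly preceding the birth month
#' (m-9 ... m-1), in chronological order. Birth timing is known to the month
#' only, so the window is whole calendar months with no day-of-birth proration.
#'
#' @param birth_year,birth_month Integers identifying the birth month m.
#' @return A `data.table` with columns `year`, `month`, `ym` (9 rows).
#' @export
gestational_window <- function(birth_year, birth_month) {
  stopifnot(length(birth_year) == 1L, length(birth_month) == 1L,
            birth_month >= 1L, birth_month <= 12L)
  ym <- ym_index(birth_year, birth_month) - (9:1)
  data.table::data.table(year = ym_year(ym), month = ym_month(ym), ym = as.integer(ym))
}

#' Daily calendar over a span of years
#'
#' @param years Integer vector of calendar years.
#' @return A `data.table` with `date`, `year`, `month`, `season`, `ym`.
#' @keywords internal
daily_calendar <- function(years) {
  years <- sort(unique(as.integer(years)))
  d <- seq(as.Date(paste0(min(years), "-01-01")),
           as.Date(paste0(max(years), "-12-31")), by = "day")
  yr <- as.integer(format(d, "%Y"))
  mo <- as.integer(format(d, "%m"))
  data.table::data.table(date = d, year = yr, month = mo,
                         season = season_of_month(mo), ym = ym_index(yr, mo))
}
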