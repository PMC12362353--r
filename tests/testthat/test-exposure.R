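library(data.table)

test_that("cumulative exceedance and day counts match hand loops", {
  wt <- c(30, 32, 28, 35, 31)
  cut <- rep(31, 5)
  # contributions 1 and 4; the day exactly at the cutoff contributes nothing
  expect_equal(cumulative_exceedance(wt, cut, "heat"), 5.0)
  expect_equal(exceedance_days(wt, cut, "heat"), 2L)

  expect_equal(cumulative_exceedance(c(20, 21, 22), rep(30, 3), "heat"), 0)
  expect_equal(cumulative_exceedance(c(10, 8, 12), rep(11, 3), "cold"), 4.0)
  expect_equal(exceedance_days(numeric(0), numeric(0), "heat"), 0L)
  expect_equal(exceedance_days(rep(40, 10), rep(39, 10), "heat"), 10L)
  expect_error(cumulative_exceedance(1:3, 1:2, "heat"), "same length")
})

test_that("exceedance is shift-equivariant in values and cutoffs", {
  set.seed(5)
  wt <- rnorm(300, 28, 3)
  cut <- rnorm(300, 29, 1)
  for (c0 in c(-3, 0.7, 12)) {
    expect_equal(cumulative_exceedance(wt + c0, cut + c0, "heat"),
                 cumulative_exceedance(wt, cut, "heat"))
    expect_equal(exceedance_days(wt + c0, cut + c0, "cold"),
                 exceedance_days(wt, cut, "cold"))
  }
})

test_that("mean precipitation over the window matches direct computation", {
  pr <- data.table(year = 2009L, month = 1:12, precip = 0)
  pr[month %in% 4:12, precip := 1:9]
  expect_equal(mean_precipitation(2010, 1, pr), 5.0)
  expect_equal(mean_precipitation(2010, 1,
                                  data.table(year = 2009L, month = 4:12, precip = 100)), 100)
  set.seed(8)
  pr2 <- data.table(year = 2012L, month = 1:12, precip = rgamma(12, 2, 0.02))
  win <- 1:9
  expect_equal(mean_precipitation(2012, 10, pr2), mean(pr2$precip[win]))
  expect_error(mean_precipitation(2010, 1, pr[month > 6]), "missing")
})

test_that("postnatal metrics cover the birth month only", {
  d <- seq(as.Date("2003-01-01"), as.Date("2006-12-31"), by = "day")
  yr <- as.integer(format(d, "%Y")); mo <- as.integer(format(d, "%m"))
  vals <- rep(25, length(d))
  june06 <- which(yr == 2006 & mo == 6)
  vals[june06[10]] <- 27  # one hot day
  wt <- data.table(cell = 1L, date = d, year = yr, month = mo,
                   season = season_of_month(mo), ym = ym_index(yr, mo), wt = vals)
  thr <- build_thresholds(wt, target_years = 2006)
  # constant reference: all cutoffs 25; the single +2 day drives everything
  post <- postnatal_exposure(2006, 6, wt, thr)
  expect_equal(post$cum_heat_75, 2.0)
  expect_equal(post$heat_days_95, 1L)
  expect_equal(post$cum_cold_25, 0)
  post0 <- postnatal_exposure(2006, 3, wt, thr)  # all days at the cutoff
  expect_true(all(unlist(post0) == 0))
  expect_error(postnatal_exposure(2007, 1, wt, thr), "not fully covered")
})

test_that("per-birth exposure records match independent per-day loops", {
  w <- toy_world()
  thr_df <- as.data.frame(w$thresholds)
  set.seed(21)
  pick <- sample(w$analysis$birth_id, 12)
  for (id in pick) {
    b <- w$analysis[birth_id == id]
    days <- w$wetbulb[cell == b$cell &
                        ym >= ym_index(b$birth_year, b$birth_month) - 9L &
                        ym <= ym_index(b$birth_year, b$birth_month) - 1L]
    setorder(days, date)
    expect_equal(nrow(days), sum(days_in_ym(
      ym_index(b$birth_year, b$birth_month) - (9:1))))
    th <- thr_df[thr_df$cell == b$cell, ]
    for (p in c(75L, 90L)) {
      o <- oracle_exposure_loop(days$date, days$wt, th, p, "heat")
      expect_equal(b[[metric_col("cumulative", p, "heat")]], o$cum)
      expect_equal(b[[metric_col("days", p, "heat")]], o$days)
    }
    o <- oracle_exposure_loop(days$date, days$wt, th, 25L, "cold")
    expect_equal(b[[metric_col("cumulative", 25, "cold")]], o$cum)
    expect_equal(b[[metric_col("days", 25, "cold")]], o$days)
  }
})

test_that("exposure metrics shrink as thresholds become more extreme", {
  a <- toy_world()$analysis
  expect_true(all(a$heat_days_75 >= a$heat_days_85 &
                    a$heat_days_85 >= a$heat_days_90 &
                    a$heat_days_90 >= a$heat_days_95))
  expect_true(all(a$cum_heat_75 >= a$cum_heat_85 &
                    a$cum_heat_85 >= a$cum_heat_90 &
                    a$cum_heat_90 >= a$cum_heat_95))
  expect_true(all(a$cold_days_25 >= a$cold_days_15 &
                    a$cold_days_15 >= a$cold_days_10 &
                    a$cold_days_10 >= a$cold_days_5))
  expect_true(all(a$cum_heat_75 >= 0) && all(a$cum_cold_25 >= 0))
  ndays <- vapply(seq_len(nrow(a)), function(i) sum(days_in_ym(
    ym_index(a$birth_year[i], a$birth_month[i]) - (9:1))), 0L)
  expect_true(all(a$heat_days_75 <= ndays))
})

test_that("whole-pipeline exposure is invariant to a uniform climate shift", {
  w <- toy_world()
  wt2 <- copy(w$wetbulb)
  wt2[, wt := wt + 4.5]
  thr2 <- build_thresholds(wt2, target_years = sort(unique(w$thresholds$year)))
  e2 <- compute_exposures(w$births, w$clusters, wt2, thr2, w$climate$precip)
  cols <- grep("^(cum_|heat_|cold_|post_)", names(w$exposures), value = TRUE)
  expect_equal(as.data.frame(e2$exposures[, ..cols]),
               as.data.frame(w$exposures[, ..cols]), tolerance = 1e-9)
})

test_that("births outside climate coverage land in the rejects report", {
  w <- toy_world()
  b <- rbind(w$births[1:3, names(w$births), with = FALSE],
             w$births[1:2, names(w$births), with = FALSE])
  b$birth_id <- c(1:3, 9001L, 9002L)
  b$birth_year[4] <- 2005L   # window needs 2004 thresholds: uncovered
  b$cluster_id[5] <- 999L    # unknown cluster
  e <- compute_exposures(b, w$clusters, w$wetbulb, w$thresholds, w$climate$precip)
  expect_equal(sort(e$rejects$birth_id), c(9001L, 9002L))
  expect_setequal(e$rejects[birth_id == 9001L, reason], "window not covered")
  expect_setequal(e$rejects[birth_id == 9002L, reason], "unknown cluster")
  expect_equal(nrow(e$exposures), 3L)
})

test_that("exposure is deterministic: same cluster and month, same record", {
  w <- toy_world()
  a <- w$analysis
  dup <- a[, .N, by = .(cluster_id, birth_year, birth_month)][N >= 2][1]
  pair <- a[cluster_id == dup$cluster_id & birth_year == dup$birth_year &
              birth_month == dup$birth_month][1:2]
  cols <- grep("^(cum_|heat_|cold_|mean_precip)", names(a), value = TRUE)
  expect_equal(as.numeric(pair[1, ..cols]), as.numeric(pair[2, ..cols]))
})
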