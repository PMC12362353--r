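# Independent oracles, written directly from first principles and kept free
# of the package's implementation paths.

# Direct transcription of the psychrometric fit (radian arctangents,
# half-integer humidity exponents), evaluated scalar-by-scalar.
oracle_stull <- function(t, rh) {
  mapply(function(ti, ri) {
    ti * atan(0.151977 * (ri + 8.313658)^0.5) +
      atan(ti + ri) -
      atan(ri - 1.676331) +
      0.00391838 * ri^(3 / 2) * atan(0.023101 * ri) -
      4.686035
  }, t, rh)
}

# Sort-based percentile with linear interpolation between order statistics:
# rank h = 1 + (n-1) * p sits between floor(h) and floor(h)+1.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Per-day loop that re-derives each day's (season, year) label and cutoff and
# accumulates both margins, for one location series.
oracle_exposure_loop <- function(dates, wt, thresholds_df, percentile, side) {
  cum <- 0
  days <- 0L
  for (i in seq_along(dates)) {
    mo <- as.integer(format(dates[i], "%m"))
    yr <- as.integer(format(dates[i], "%Y"))
    seas <- (mo - 1) %/% 3 + 1
    row <- thresholds_df[thresholds_df$season == seas &
                           thresholds_df$year == yr &
                           thresholds_df$percentile == percentile, ]
    stopifnot(nrow(row) == 1)
    cut <- row$cutoff
    if (side == "heat") {
      if (wt[i] > cut) { cum <- cum + (wt[i] - cut); days <- days + 1L }
    } else {
      if (wt[i] < cut) { cum <- cum + (cut - wt[i]); days <- days + 1L }
    }
  }
  list(cum = cum, days = days)
}

# Explicit dummy-variable least squares: outcome on regressors plus one dummy
# per factor level (intercept included), via lm(). Returns slope estimates on
# the named regressors and the fitted lm object.
oracle_dummy_ols <- function(data, outcome, regressors, factor_cols) {
  fml <- stats::as.formula(paste(
    outcome, "~",
    paste(c(regressors, paste0("factor(", factor_cols, ")")), collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  list(coef = stats::coef(fit)[regressors], fit = fit)
}

# Direct CR1 sandwich from score vectors, written out in full.
oracle_cluster_sandwich <- function(X, e, cluster, k_eff) {
  X <- as.matrix(X)
  n <- nrow(X)
  bread <- solve(t(X) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    sg <- colSums(X[cluster == g, , drop = FALSE] * e[cluster == g])
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cluster))
  (G / (G - 1)) * ((n - 1) / (n - k_eff)) * bread %*% meat %*% bread
}
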