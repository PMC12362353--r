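library(data.table)

make_panel <- function(n = 600, n_id = 30, n_time = 10, seed = 1) {
  set.seed(seed)
  d <- data.table(
    id = sample.int(n_id, n, TRUE),
    time = sample.int(n_time, n, TRUE),
    grp = sample.int(8, n, TRUE))
  d[, x1 := rnorm(n) + 0.5 * id / n_id]
  d[, x2 := rnorm(n) - 0.3 * time / n_time]
  d[, y := 1.5 * x1 - 2 * x2 + rnorm(n_id)[id] + rnorm(n_time)[time] + rnorm(n)]
  d
}

test_that("single-factor demeaning is exact one-pass group centering", {
  d <- make_panel()
  M <- within_transform(as.matrix(d[, .(y, x1)]), list(d$id))
  for (g in unique(d$id)) {
    expect_equal(mean(M[d$id == g, "y"]), 0, tolerance = 1e-12)
  }
  expect_equal(as.numeric(M[, "x1"]),
               d$x1 - ave(d$x1, d$id), tolerance = 1e-12)
  # idempotence
  M2 <- within_transform(M, list(d$id))
  expect_equal(unclass(M2), unclass(M), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("multi-factor absorption equals explicit dummy-variable projection", {
  d <- make_panel(n = 480, n_id = 12, n_time = 8, seed = 3)
  M <- within_transform(as.matrix(d[, .(y, x1, x2)]),
                        list(d$id, d$time), tol = 1e-12)
  # residuals from projecting each column on the dummy span
  for (col in c("y", "x1", "x2")) {
    r <- resid(lm(d[[col]] ~ factor(d$id) + factor(d$time)))
    expect_equal(as.numeric(M[, col]), as.numeric(r), tolerance = 1e-10)
  }
  # a column constant within groups of one factor is annihilated
  d[, cwithin := as.numeric(id)]
  Mc <- within_transform(as.matrix(d[, .(cwithin)]), list(d$id, d$time))
  expect_lt(max(abs(Mc)), 1e-8)
})

test_that("absorbed-FE slopes match dummy-variable least squares", {
  d <- make_panel(n = 900, n_id = 25, n_time = 12, seed = 9)
  d[, cell := grp]
  spec <- fe_spec("y", c("x1", "x2"), fe = list("id", "time", "cell"),
                  cluster = "id")
  fit <- fit_fe_lpm(spec, d)
  o <- oracle_dummy_ols(d, "y", c("x1", "x2"), c("id", "time", "cell"))
  expect_equal(fit$table$estimate, unname(o$coef), tolerance = 1e-6)
  # exact-fit sanity: y = 2x with one factor
  d2 <- data.table(y = 2 * (1:40), x = as.numeric(1:40),
                   f = rep(1:4, each = 10), cl = rep(1:8, each = 5))
  f2 <- fit_fe_lpm(fe_spec("y", "x", fe = list("f"), cluster = "cl"), d2)
  expect_equal(f2$table$estimate, 2.0, tolerance = 1e-10)
})

test_that("residuals are orthogonal to the demeaned regressors", {
  d <- make_panel(seed = 5)
  M <- within_transform(as.matrix(d[, .(y, x1, x2)]), list(d$id, d$time))
  f <- ols_fit(M[, 1], M[, -1])
  ip <- abs(crossprod(M[, -1], f$residuals))
  expect_true(all(ip <= 1e-8 * nrow(d) * apply(abs(M[, -1]), 2, max)))
})

test_that("a regressor absorbed by its own factor triggers a rank error", {
  d <- make_panel()
  d[, xconst := as.numeric(id) * 3.2]  # constant within cluster FE
  spec <- fe_spec("y", c("x1", "xconst"), fe = list("id"), cluster = "id")
  expect_error(fit_fe_lpm(spec, d), "collinear.*xconst")
})

test_that("cluster-robust vcov matches the hand-computed sandwich", {
  # 3-cluster toy, fully written out in the oracle
  set.seed(13)
  X <- cbind(a = rnorm(12), b = rnorm(12))
  e <- rnorm(12)
  cl <- rep(1:3, each = 4)
  vc <- cluster_robust_vcov(X, e, cl, k_eff = 2)
  expect_equal(unclass(vc$vcov), unclass(oracle_cluster_sandwich(X, e, cl, 2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(cluster_robust_vcov(X, e, rep(1, 12), 2), "at least 2 clusters")
})

test_that("singleton clusters collapse the sandwich to HC1", {
  set.seed(17)
  n <- 80
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  e <- rnorm(n) * (1 + 0.5 * abs(X[, 1]))
  k <- 2
  vc <- cluster_robust_vcov(X, e, seq_len(n), k_eff = k)
  XtXi <- solve(crossprod(X))
  hc1 <- (n / (n - k)) * XtXi %*% crossprod(X * e) %*% XtXi
  expect_equal(unclass(vc$vcov), unclass(hc1), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("fitted standard errors agree with an independent clustered-OLS oracle", {
  skip_if_not_installed("sandwich")
  d <- make_panel(n = 700, n_id = 20, n_time = 6, seed = 23)
  spec <- fe_spec("y", c("x1", "x2"), fe = list("id", "time"), cluster = "id")
  fit <- fit_fe_lpm(spec, d)
  o <- oracle_dummy_ols(d, "y", c("x1", "x2"), c("id", "time"))
  vc <- sandwich::vcovCL(o$fit, cluster = d$id, type = "HC1", cadjust = TRUE)
  expect_equal(fit$table$estimate, unname(o$coef), tolerance = 1e-8)
  expect_equal(fit$table$se, unname(sqrt(diag(vc)[c("x1", "x2")])),
               tolerance = 1e-6)
})

test_that("slopes are invariant to row duplication and location shifts", {
  d <- make_panel(seed = 31)
  spec <- fe_spec("y", c("x1", "x2"), fe = list("id", "time"), cluster = "id")
  f1 <- fit_fe_lpm(spec, d)
  f2 <- fit_fe_lpm(spec, rbind(d, d))
  expect_equal(f2$table$estimate, f1$table$estimate, tolerance = 1e-10)
  d3 <- copy(d); d3[, y := y + 1000]
  expect_equal(fit_fe_lpm(spec, d3)$table$estimate, f1$table$estimate,
               tolerance = 1e-8)
  d4 <- copy(d); d4[, y := y + rnorm(max(id))[id] * 50]  # cluster-level shift
  expect_equal(fit_fe_lpm(spec, d4)$table$estimate, f1$table$estimate,
               tolerance = 1e-7)
})

test_that("degenerate outcomes give zero slopes with a warning", {
  d <- make_panel(seed = 41)
  d[, yc := 5]
  spec <- fe_spec("yc", "x1", fe = list("id"), cluster = "id")
  expect_warning(f <- fit_fe_lpm(spec, d), "no within-group variation")
  expect_equal(f$table$estimate, 0, tolerance = 1e-10)
})

test_that("confidence intervals cover a planted slope at close to nominal rate", {
  set.seed(53)
  hits <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    ng <- 40; m <- 8
    id <- rep(seq_len(ng), each = m)
    x <- rnorm(ng * m)
    y <- 0.7 * x + rnorm(ng)[id] + rnorm(ng * m)
    d <- data.table(y = y, x = x, id = id, t = rep(seq_len(m), ng))
    f <- fit_fe_lpm(fe_spec("y", "x", fe = list("id"), cluster = "id"), d)
    if (f$table$ci_lo <= 0.7 && 0.7 <= f$table$ci_hi) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.88)
  expect_lte(hits / reps, 0.995)
})
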