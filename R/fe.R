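# High-dimensional fixed-effects linear regression by iterated demeaning
# (alternating projections), with CR1 cluster-robust inference.
#
# The route is Frisch-Waugh: partial every submitted column on the span of the
# fixed-effect dummies by sweeping group demeaning over the factors until all
# group means vanish, then run OLS on the residualized columns.

#' Within transformation: absorb fixed-effect factors by iterated demeaning
#'
#' Repeatedly subtracts group means of every column under every factor until
#' the largest absolute group mean is below `tol` (alternating projections
#' onto the orthocomplement of each factor's dummy span). With a single
#' factor this is exact one-pass group demeaning.
#'
#' @param x Numeric matrix (or data.frame of numerics), observations in rows.
#' @param factors List of factor/integer vectors, one per fixed-effect factor,
#'   each of length `nrow(x)`.
#' @param tol Convergence tolerance on the max absolute group mean
#'   (default 1e-10).
#' @param max_iter Maximum number of full sweeps (default 10000).
#' @return The demeaned matrix, with attributes `iterations` and
#'   `max_group_mean` (final worst group mean).
#' @export
within_transform <- function(x, factors, tol = 1e-10, max_iter = 10000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing values in columns submitted for demeaning", call. = FALSE)
  if (!is.list(factors)) factors <- list(factors)
  ids <- lapply(factors, function(f) {
    f <- as.integer(factor(f))
    if (length(f) != nrow(x)) stop("factor length does not match rows", call. = FALSE)
    f
  })
  counts <- lapply(ids, tabulate)
  it <- 0L
  worst <- Inf
  repeat {
    it <- it + 1L
    for (j in seq_along(ids)) {
      gm <- rowsum(x, ids[[j]], reorder = TRUE) / counts[[j]]
      x <- x - gm[ids[[j]], , drop = FALSE]
    }
    worst <- 0
    for (j in seq_along(ids)) {
      gm <- rowsum(x, ids[[j]], reorder = TRUE) / counts[[j]]
      w <- max(abs(gm))
      if (w > worst) { worst <- w; worst_factor <- j }
    }
    if (worst <= tol) break
    if (it >= max_iter) {
      stop(sprintf(
        "demeaning did not converge in %d sweeps (worst group mean %.3e on factor %d)",
        max_iter, worst, worst_factor), call. = FALSE)
    }
  }
  attr(x, "iterations") <- it
  attr(x, "max_group_mean") <- worst
  x
}

#' OLS on demeaned outcome and regressors
#'
#' @param y Demeaned outcome vector.
#' @param X Demeaned regressor matrix (named columns).
#' @return `list(coefficients, residuals, XtX_inv, rank)`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop(sprintf(
      "rank-deficient regressor matrix after absorption; collinear column(s): %s (possibly constant within a fixed-effect factor)",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  resid <- as.numeric(y - X %*% beta)
  list(coefficients = beta, residuals = resid,
       XtX_inv = chol2inv(chol(crossprod(X))), rank = qr_x$rank)
}

#' Cluster-robust (CR1) sandwich variance
#'
#' Sandwich estimator `(X'X)^-1 (sum_g s_g s_g') (X'X)^-1` where `s_g` sums
#' the per-observation scores `x_i e_i` within cluster `g`, scaled by the CR1
#' small-sample factor `[G/(G-1)] * [(n-1)/(n-k_eff)]`. With every cluster a
#' singleton this collapses to the HC1 heteroskedasticity-robust form.
#'
#' @param X Demeaned regressor matrix.
#' @param residuals OLS residual vector.
#' @param cluster Cluster id vector (length `nrow(X)`).
#' @param k_eff Effective number of estimated parameters: slopes plus absorbed
#'   fixed-effect degrees of freedom (including one shared intercept).
#' @param XtX_inv Optional precomputed `(X'X)^-1`.
#' @return `list(vcov, n_clusters, cr1)`.
#' @export
cluster_robust_vcov <- function(X, residuals, cluster, k_eff, XtX_inv = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  g <- as.integer(factor(cluster))
  G <- max(g)
  if (G < 2L) stop("cluster-robust inference requires at least 2 clusters", call. = FALSE)
  if (is.null(XtX_inv)) XtX_inv <- chol2inv(chol(crossprod(X)))
  S <- rowsum(X * residuals, g, reorder = FALSE)
  meat <- crossprod(S)
  cr1 <- (G / (G - 1)) * ((n - 1) / (n - k_eff))
  list(vcov = cr1 * XtX_inv %*% meat %*% XtX_inv, n_clusters = G, cr1 = cr1)
}

#' Specify an absorbed fixed-effects linear probability model
#'
#' @param outcome Outcome column name.
#' @param exposure Character vector of exposure regressor names.
#' @param controls Character vector of control names (default empty).
#' @param fe List of fixed-effect factors; each element is a character vector
#'   of column names whose interaction defines one factor. Default: DHS
#'   cluster; birth year; 2-degree cell x birth month.
#' @param cluster Column to cluster standard errors on (default
#'   `"cluster_id"`).
#' @param scale_outcome Multiply the outcome by 1000 before fitting (used for
#'   the 0/1 mortality indicator so coefficients read as deaths per 1,000
#'   births). Default `FALSE`.
#' @param filter Optional one-sided formula or expression evaluated in the
#'   data, selecting the estimation subsample.
#' @param drop_singletons Drop observations alone in a fixed-effect group
#'   (default `FALSE`; singletons are retained but always counted in the
#'   absorbed degrees of freedom).
#' @param tol,max_iter Demeaning convergence controls.
#' @return An object of class `fe_spec`.
#' @export
fe_spec <- function(outcome, exposure, controls = character(0),
                    fe = list("cluster_id", "birth_year", c("cell2", "birth_month")),
                    cluster = "cluster_id", scale_outcome = FALSE,
                    filter = NULL, drop_singletons = FALSE,
                    tol = 1e-10, max_iter = 10000L) {
  stopifnot(length(outcome) == 1L, length(exposure) >= 1L)
  structure(list(outcome = outcome, exposure = exposure, controls = controls,
                 fe = fe, cluster = cluster, scale_outcome = scale_outcome,
                 filter = filter, drop_singletons = drop_singletons,
                 tol = tol, max_iter = max_iter),
            class = "fe_spec")
}

#' Fit an absorbed fixed-effects linear probability model
#'
#' Applies the sample filter, optionally scales the outcome by 1000, absorbs
#' the fixed-effect factors by iterated demeaning, estimates the slopes by
#' OLS, and computes CR1 cluster-robust standard errors with `G - 1`
#' t-distribution degrees of freedom for tests and 95% confidence intervals.
#'
#' Absorbed degrees of freedom are counted as `1 + sum(levels - 1)` over the
#' factors — exact for a single factor and for connected crossed factors
#' sharing only the intercept, an approximation otherwise (recorded in the
#' result).
#'
#' @param spec An [fe_spec()].
#' @param data A `data.table`/data.frame holding every referenced column.
#' @return An object of class `fe_fit`: `table` (one row per regressor:
#'   estimate, se, t, p, ci_lo, ci_hi), `n`, `n_clusters`, `n_groups`,
#'   `k_eff`, `iterations`, `max_group_mean`, `n_singletons`, `spec`.
#' @export
fit_fe_lpm <- function(spec, data) {
  stopifnot(inherits(spec, "fe_spec"))
  dt <- data.table::as.data.table(data)
  if (!is.null(spec$filter)) {
    e <- if (inherits(spec$filter, "formula")) spec$filter[[2]] else spec$filter
    keep <- eval(e, envir = dt, enclos = parent.frame())
    dt <- dt[keep & !is.na(keep)]
  }
  need <- unique(c(spec$outcome, spec$exposure, spec$controls,
                   unlist(spec$fe), spec$cluster))
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dt) == 0L) stop("empty estimation sample after filtering", call. = FALSE)
  dt <- dt[stats::complete.cases(dt[, need, with = FALSE])]
  if (nrow(dt) == 0L) stop("empty estimation sample after dropping missing values", call. = FALSE)

  factors <- lapply(spec$fe, function(cols) {
    if (length(cols) == 1L) dt[[cols]]
    else interaction(dt[, cols, with = FALSE], drop = TRUE, lex.order = TRUE)
  })
  ids <- lapply(factors, function(f) as.integer(factor(f)))
  n_singletons <- sum(vapply(ids, function(f) sum(tabulate(f) == 1L), 0L))
  if (spec$drop_singletons && n_singletons > 0L) {
    repeat {
      keep <- rep(TRUE, nrow(dt))
      for (f in ids) keep <- keep & tabulate(f)[f] > 1L
      if (all(keep)) break
      dt <- dt[keep]
      ids <- lapply(ids, function(f) as.integer(factor(f[keep])))
    }
  }

  y <- dt[[spec$outcome]]
  if (spec$scale_outcome) y <- y * 1000
  xcols <- c(spec$exposure, spec$controls)
  M <- cbind(y = y, as.matrix(dt[, xcols, with = FALSE]))
  Md <- within_transform(M, ids, tol = spec$tol, max_iter = spec$max_iter)
  yd <- Md[, 1]
  Xd <- Md[, -1, drop = FALSE]
  colnames(Xd) <- xcols
  # a regressor with no within-group variation is absorbed by the FEs
  pre_scale <- apply(abs(M[, -1, drop = FALSE]), 2, max)
  post_scale <- apply(abs(Xd), 2, max)
  dead <- post_scale < 1e-10 * (pre_scale + 1)
  if (any(dead)) {
    stop("rank-deficient after absorption; collinear column(s) absorbed by the fixed effects: ",
         paste(xcols[dead], collapse = ", "), call. = FALSE)
  }

  if (all(abs(yd) < 1e-12)) {
    warning("outcome has no within-group variation; slopes are zero and standard errors degenerate")
  }
  fit <- ols_fit(yd, Xd)
  n_groups <- vapply(ids, max, 0L)
  k_eff <- length(xcols) + 1L + sum(n_groups - 1L)
  vc <- cluster_robust_vcov(Xd, fit$residuals, dt[[spec$cluster]], k_eff,
                            XtX_inv = fit$XtX_inv)
  se <- sqrt(diag(vc$vcov))
  df <- vc$n_clusters - 1L
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  crit <- stats::qt(0.975, df = df)
  tab <- data.table::data.table(
    term = xcols,
    estimate = as.numeric(fit$coefficients),
    se = se, t = as.numeric(tval), p = as.numeric(pval),
    ci_lo = as.numeric(fit$coefficients - crit * se),
    ci_hi = as.numeric(fit$coefficients + crit * se))
  structure(list(table = tab, vcov = vc$vcov, n = nrow(dt),
                 n_clusters = vc$n_clusters, n_groups = n_groups,
                 k_eff = k_eff, df = df,
                 iterations = attr(Md, "iterations"),
                 max_group_mean = attr(Md, "max_group_mean"),
                 n_singletons = n_singletons,
                 dof_note = "absorbed dof = 1 + sum(levels - 1); approximate for non-nested crossed factors",
                 spec = spec),
            class = "fe_fit")
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("Absorbed-FE linear model: n = %d, clusters = %d, absorbed groups = %s\n",
              x$n, x$n_clusters, paste(x$n_groups, collapse = "/")))
  print(x$table, digits = 4)
  invisible(x)
}
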