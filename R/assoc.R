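#' Covariate-adjusted ordinary least squares for one focal predictor
#'
#' Fits `y ~ intercept + x + covariates` by OLS on the listwise-complete
#' cases and reports the focal-predictor coefficient with its standard
#' error, t statistic and two-sided p value from the t distribution with
#' `df = n - #regressors`.
#'
#' @param y numeric response vector.
#' @param x numeric focal predictor (e.g. a SNP gene-dose or an expression
#'   trait). Must be non-constant on the complete cases.
#' @param covariates optional covariate set: a [covariate_table], data frame
#'   or numeric matrix aligned with `y`.
#' @return an object of class `ols_fit`: a list with elements `beta`, `se`,
#'   `t`, `p`, `df`, `n`, `beta_covariates` (named vector incl. intercept),
#'   and `explained_var` (partial R-squared of the focal predictor,
#'   `t^2 / (t^2 + df)`).
#' @examples
#' fit_ols(c(1, 2, 3, 4), c(0, 1, 2, 3))
#' @export
fit_ols <- function(y, x, covariates = NULL) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  stopifnot(length(x) == length(y))
  C <- as_covariate_matrix(covariates, n = length(y))
  ok <- is.finite(y) & is.finite(x)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  n <- sum(ok)
  X <- cbind(`(Intercept)` = 1, x = x[ok])
  if (!is.null(C)) X <- cbind(X, C[ok, , drop = FALSE])
  if (n < ncol(X) + 2L) {
    stop("too few complete cases (", n, ") for ", ncol(X), " regressors")
  }
  if (stats::var(x[ok]) == 0) stop("monomorphic predictor: focal x is constant")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  beta_all <- qr.coef(qx, y[ok])
  res <- qr.resid(qx, y[ok])
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  # unscaled covariance from the R factor, undoing the pivot
  Rinv <- chol2inv(qr.R(qx))
  vc <- numeric(ncol(X))
  vc[qx$pivot] <- diag(Rinv)
  se_all <- sqrt(sigma2 * vc)
  tval <- beta_all[["x"]] / se_all[[which(colnames(X) == "x")]]
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(
    beta = unname(beta_all[["x"]]),
    se = unname(se_all[[which(colnames(X) == "x")]]),
    t = unname(tval),
    p = unname(p),
    df = df,
    n = n,
    beta_covariates = beta_all[names(beta_all) != "x"],
    explained_var = partial_r2(tval, df)
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "OLS fit: beta = %.6g (SE %.3g), t = %.3f, p = %.3g, n = %d, df = %d, partial R2 = %.3g\n",
    x$beta, x$se, x$t, x$p, x$n, x$df, x$explained_var
  ))
  invisible(x)
}

#' Partial explained variance of a focal predictor
#'
#' The variance a focal predictor explains on top of the covariates,
#' computed from its t statistic as `t^2 / (t^2 + df)`. This equals the
#' partial R-squared `(RSS_reduced - RSS_full) / RSS_reduced` of the
#' two-model comparison.
#'
#' @param t focal-predictor t statistic.
#' @param df residual degrees of freedom of the full model.
#' @return fraction in `[0, 1)`.
#' @export
partial_r2 <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  t^2 / (t^2 + df)
}

#' Jackknife standard error of an arbitrary statistic
#'
#' Leave-one-out jackknife:
#' `SE = sqrt(((n - 1) / n) * sum_i (theta_(-i) - mean(theta_(-.)))^2)`.
#'
#' @param statistic function taking the data restricted to a subset of
#'   units and returning a numeric scalar.
#' @param data the sample: a vector or list (units = elements) or a matrix
#'   or data frame (units = rows).
#' @return the jackknife standard error (nonnegative scalar).
#' @export
jackknife_se <- function(statistic, data) {
  n <- if (is.matrix(data) || is.data.frame(data)) nrow(data) else length(data)
  if (n < 3L) stop("jackknife requires n >= 3")
  subset_fn <- if (is.matrix(data) || is.data.frame(data)) {
    function(i) data[-i, , drop = FALSE]
  } else {
    function(i) data[-i]
  }
  theta <- vapply(seq_len(n), function(i) {
    val <- tryCatch(statistic(subset_fn(i)),
      error = function(e) stop("leave-one-out evaluation failed at index ", i,
        ": ", conditionMessage(e)))
    as.numeric(val)
  }, numeric(1))
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

#' Genomic inflation factor
#'
#' Lambda is the median association chi-square (1 df) divided by the null
#' median 0.4549364. Values near 1 indicate no systematic inflation such as
#' population stratification.
#'
#' @param pvals vector of p values in (0, 1].
#' @return positive scalar lambda.
#' @export
genomic_lambda <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p values must lie in (0, 1]")
  }
  stats::median(stats::qchisq(pvals, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

# Coerce the accepted covariate representations to a plain numeric matrix
# (NULL stays NULL). Factors/characters are not expanded: callers pass
# numeric-coded covariates (binary as 0/1), matching the cohort tables.
as_covariate_matrix <- function(covariates, n = NULL) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "covariate_table")) {
    m <- as.matrix(covariates$data)
  } else if (is.data.frame(covariates)) {
    m <- as.matrix(covariates)
  } else {
    m <- as.matrix(covariates)
  }
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("cov", seq_len(ncol(m)))
  if (!is.null(n) && nrow(m) != n) stop("covariate rows do not match sample count")
  m
}

#' Vectorised association scan of many traits against many predictors
#'
#' Exact per-pair OLS of each trait on each focal predictor plus the shared
#' covariates, computed by the Frisch-Waugh projection: residualize the
#' trait and the predictors on `[1, covariates]` over that trait's complete
#' cases, then a simple regression with `df = n_complete - #covariates - 2`.
#' Results are identical to calling [fit_ols()] pair by pair.
#'
#' @param X numeric matrix, samples x predictors (no missing values).
#' @param Y numeric matrix, samples x traits (NA allowed; listwise per trait).
#' @param covariates optional covariates (see [fit_ols()]).
#' @param layer label stored in the output records.
#' @return data frame of association records: `x_id`, `y_id`, `layer`,
#'   `beta`, `se`, `t`, `p`, `n`, `df`, `explained_var`. Monomorphic
#'   predictors within a trait's complete cases yield NA statistics.
#' @export
assoc_scan <- function(X, Y, covariates = NULL, layer = "assoc") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  C <- as_covariate_matrix(covariates, n = nrow(X))
  core <- scan_core(X, Y, C)
  xid <- colnames(X); if (is.null(xid)) xid <- paste0("x", seq_len(ncol(X)))
  yid <- colnames(Y); if (is.null(yid)) yid <- paste0("y", seq_len(ncol(Y)))
  k <- ncol(X); q <- ncol(Y)
  df <- rep(core$df, each = k)
  tval <- as.vector(core$t)
  res <- data.frame(
    x_id = rep(xid, times = q),
    y_id = rep(yid, each = k),
    layer = layer,
    beta = as.vector(core$beta),
    se = as.vector(core$se),
    t = tval,
    p = 2 * stats::pt(-abs(tval), pmax(df, 1)),
    n = rep(core$n, each = k),
    df = df,
    explained_var = tval^2 / (tval^2 + df),
    stringsAsFactors = FALSE)
  res$p[df < 1] <- NA_real_
  rownames(res) <- NULL
  res
}

# Fast exact scan core: beta/se/t as k x q matrices, df and n per trait.
# Per trait, complete cases are taken listwise, the trait and all focal
# predictors are projected off [1, C], and the simple-regression formulas
# applied; identical to per-pair fit_ols.
scan_core <- function(X, Y, C = NULL) {
  if (anyNA(X)) stop("predictors must be complete; impute or drop first")
  k <- ncol(X); q <- ncol(Y)
  beta <- se <- tval <- matrix(NA_real_, k, q)
  df <- n <- integer(q)
  base_ok <- if (is.null(C)) rep(TRUE, nrow(X)) else stats::complete.cases(C)
  complete_y <- !anyNA(Y[base_ok, , drop = FALSE])
  pcol <- 1L + if (is.null(C)) 0L else ncol(C)
  if (complete_y) {
    # one shared projection for all traits
    ok <- base_ok
    Cj <- cbind(rep(1, sum(ok)), if (is.null(C)) NULL else C[ok, , drop = FALSE])
    qc <- qr(Cj)
    Xr <- qr.resid(qc, X[ok, , drop = FALSE])
    Yr <- qr.resid(qc, Y[ok, , drop = FALSE])
    sxx <- colSums(Xr^2)
    syy <- colSums(Yr^2)
    sxy <- crossprod(Xr, Yr)                       # k x q
    df[] <- sum(ok) - pcol - 1L
    n[] <- sum(ok)
    beta <- sxy / sxx
    rss <- matrix(syy, k, q, byrow = TRUE) - beta * sxy
    se <- sqrt(pmax(rss, 0) / df[1] / sxx)
    tval <- beta / se
    mono <- sxx < 1e-12 * sum(ok)
    beta[mono, ] <- se[mono, ] <- tval[mono, ] <- NA_real_
  } else {
    for (j in seq_len(q)) {
      ok <- base_ok & is.finite(Y[, j])
      n[j] <- sum(ok)
      df[j] <- n[j] - pcol - 1L
      if (df[j] < 1L) next
      Cj <- cbind(rep(1, n[j]), if (is.null(C)) NULL else C[ok, , drop = FALSE])
      qc <- qr(Cj)
      yr <- qr.resid(qc, Y[ok, j])
      Xr <- qr.resid(qc, X[ok, , drop = FALSE])
      sxx <- colSums(Xr^2)
      sxy <- drop(crossprod(Xr, yr))
      b <- sxy / sxx
      rss <- sum(yr^2) - b * sxy
      s <- sqrt(pmax(rss, 0) / df[j] / sxx)
      mono <- sxx < 1e-12 * n[j]
      b[mono] <- s[mono] <- NA_real_
      beta[, j] <- b; se[, j] <- s; tval[, j] <- b / s
    }
  }
  list(beta = beta, se = se, t = tval, df = df, n = n)
}
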