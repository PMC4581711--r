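## Adapted Mendelian randomization on SNP-residualized metabolites and the
## jackknife beta-attenuation mediation test, per association triangle.

# Focal-coefficient leave-one-out values for an OLS fit, via the exact
# case-deletion identity beta_(-i) = beta - (X'X)^{-1} x_i e_i / (1 - h_i)
# (identical to refitting without row i; verified against brute force in
# the tests). Returns list(beta, loo) with loo a length-n vector.
loo_focal_beta <- function(X, y, focal) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design in leave-one-out computation")
  beta <- qr.coef(qx, y)
  e <- qr.resid(qx, y)
  Rinv <- chol2inv(qr.R(qx))
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[qx$pivot, qx$pivot] <- Rinv
  U <- X %*% XtXinv
  h <- rowSums(U * X)
  if (any(h >= 1 - 1e-10)) stop("leverage 1 encountered; leave-one-out undefined")
  list(beta = beta[focal], loo = beta[focal] - U[, focal] * e / (1 - h))
}

jack_se_from_loo <- function(theta) {
  n <- length(theta)
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

causal_design <- function(g, e, y, covariates) {
  C <- as_covariate_matrix(covariates, n = length(g))
  ok <- is.finite(g) & is.finite(e) & is.finite(y)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  if (sum(ok) < 30) stop("fewer than 30 complete cases")
  list(g = g[ok], e = e[ok], y = y[ok],
    C = if (is.null(C)) NULL else C[ok, , drop = FALSE], n = sum(ok))
}

#' Adapted Mendelian randomization with jackknife standard errors
#'
#' Uses the SNP as an instrument for the expression-to-metabolite effect,
#' adapted for a possible direct SNP effect on the metabolite: (1) fit
#' `y ~ g + e + covariates` and take the direct SNP coefficient `c`;
#' (2) residualize the metabolite, `y* = y - c g`; (3) the MR effect is
#' the covariate-adjusted IV ratio `beta(y* ~ g + C) / beta(e ~ g + C)`.
#' Under a direct-plus-mediated data-generating model this recovers the
#' expression effect despite the direct path. The standard error is the
#' leave-one-out jackknife of the full three-step computation (evaluated
#' through exact case-deletion identities); the p value is the two-sided
#' normal test of `beta_mr / se_jack`.
#'
#' @param g SNP dose vector (instrument).
#' @param e expression vector (exposure).
#' @param y metabolite vector (outcome).
#' @param covariates optional covariate set.
#' @return an object of class `mr_result`: list with `beta_mr`,
#'   `se_jack`, `p`, `direct_beta_removed`, `instrument_t`,
#'   `weak_instrument`, `n`.
#' @export
mr_adapted <- function(g, e, y, covariates = NULL) {
  d <- causal_design(g, e, y, covariates)
  Xge <- cbind(1, g = d$g, e = d$e, d$C)
  Xg <- cbind(1, g = d$g, d$C)
  f_c <- loo_focal_beta(Xge, d$y, focal = 2L)       # direct SNP coefficient
  f_yg <- loo_focal_beta(Xg, d$y, focal = 2L)       # total SNP effect on y
  f_eg <- loo_focal_beta(Xg, d$e, focal = 2L)       # instrument relevance
  # instrument t from the e ~ g + C fit
  fit_e <- fit_ols(d$e, d$g, d$C)
  weak <- abs(fit_e$t) < 2
  if (abs(f_eg$beta) < .Machine$double.eps^0.5) {
    stop("zero instrument-exposure coefficient; MR ratio undefined")
  }
  beta_mr <- (f_yg$beta - f_c$beta) / f_eg$beta
  theta <- (f_yg$loo - f_c$loo) / f_eg$loo
  se <- jack_se_from_loo(theta)
  p <- if (weak) NA_real_ else 2 * stats::pnorm(-abs(beta_mr / se))
  structure(list(beta_mr = unname(beta_mr), se_jack = se, p = p,
    direct_beta_removed = unname(f_c$beta),
    instrument_t = fit_e$t, instrument_p = fit_e$p,
    weak_instrument = weak, n = d$n), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("adapted MR: beta = %.4g (jackknife SE %.3g), p = %.3g, n = %d%s\n",
    x$beta_mr, x$se_jack, x$p, x$n,
    if (x$weak_instrument) " [weak instrument]" else ""))
  invisible(x)
}

#' Beta-attenuation mediation test with jackknife standard errors
#'
#' Tests whether the transcript explains part of the SNP-metabolite
#' association: fit the SNP model without (`y ~ g + C`) and with
#' (`y ~ g + e + C`) the expression term on the same complete-case
#' samples, and test `delta = |beta_without| - |beta_with|` against zero
#' using the leave-one-out jackknife of the full two-model computation.
#' A significantly positive delta means the expression accounts for a
#' nominally significant part of the SNP effect.
#'
#' @inheritParams mr_adapted
#' @return an object of class `mediation_result`: list with
#'   `beta_without`, `beta_with`, `delta`, `se_jack_delta`, `p_delta`,
#'   `n`.
#' @export
mediation_attenuation_test <- function(g, e, y, covariates = NULL) {
  d <- causal_design(g, e, y, covariates)
  f_wo <- loo_focal_beta(cbind(1, g = d$g, d$C), d$y, focal = 2L)
  f_wi <- loo_focal_beta(cbind(1, g = d$g, e = d$e, d$C), d$y, focal = 2L)
  delta <- abs(f_wo$beta) - abs(f_wi$beta)
  theta <- abs(f_wo$loo) - abs(f_wi$loo)
  se <- jack_se_from_loo(theta)
  p <- 2 * stats::pnorm(-abs(delta / se))
  structure(list(beta_without = unname(f_wo$beta), beta_with = unname(f_wi$beta),
    delta = unname(delta), se_jack_delta = se, p_delta = p, n = d$n),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "mediation: beta %.4g -> %.4g, delta = %.4g (jackknife SE %.3g), p = %.3g, n = %d\n",
    x$beta_without, x$beta_with, x$delta, x$se_jack_delta, x$p_delta, x$n))
  invisible(x)
}

#' Causal summary over association triangles
#'
#' One row per (SNP, gene, metabolite) triangle: the three association
#' betas and explained variances (copied from the triangle's edges), the
#' adapted-MR estimate with its jackknife p, and the mediation delta with
#' its jackknife p. The best triple per locus (minimal mediation p) is
#' flagged. Conclusions about causality should rest on the mediation
#' test, the more conservative of the two.
#'
#' @param triangles triangle records from [build_triangles()].
#' @param G [genotype_matrix()], `E` prepared [expression_matrix()],
#'   `panel` prepared [metabolite_panel()] and `covariates` on a common
#'   sample set (use [harmonize_samples()]).
#' @param E,panel,covariates see above.
#' @param locus_map optional data frame (`snp_id`, `locus_id`).
#' @return data frame in a per-triangle report layout.
#' @export
summarize_causal <- function(triangles, G, E, panel, covariates = NULL,
                             locus_map = NULL) {
  if (nrow(triangles) == 0) {
    return(data.frame(snp_id = character(), probe_id = character(),
      metabolite = character(), locus_id = character(),
      beta_mqtl = numeric(), r2_mqtl = numeric(),
      beta_eqtl = numeric(), r2_eqtl = numeric(),
      beta_exprmet = numeric(), r2_exprmet = numeric(),
      beta_mr = numeric(), se_mr = numeric(), p_mr = numeric(),
      delta = numeric(), se_delta = numeric(), p_mediation = numeric(),
      n = integer(), best_in_locus = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(triangles)), function(i) {
    tr <- triangles[i, ]
    g <- G$doses[, tr$snp_id]
    e <- E$values[, tr$probe_id]
    y <- panel$values[, tr$metabolite]
    mr <- mr_adapted(g, e, y, covariates)
    med <- mediation_attenuation_test(g, e, y, covariates)
    data.frame(snp_id = tr$snp_id, probe_id = tr$probe_id,
      metabolite = tr$metabolite,
      locus_id = if (!is.null(locus_map)) {
        locus_map$locus_id[match(tr$snp_id, locus_map$snp_id)]
      } else NA_character_,
      beta_mqtl = tr$beta_mqtl, r2_mqtl = tr$r2_mqtl,
      beta_eqtl = tr$beta_eqtl, r2_eqtl = tr$r2_eqtl,
      beta_exprmet = tr$beta_exprmet, r2_exprmet = tr$r2_exprmet,
      beta_mr = mr$beta_mr, se_mr = mr$se_jack, p_mr = mr$p,
      delta = med$delta, se_delta = med$se_jack_delta,
      p_mediation = med$p_delta, n = med$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$best_in_locus <- FALSE
  grp <- if (all(is.na(out$locus_id))) out$snp_id else out$locus_id
  for (g in unique(grp)) {
    idx <- which(grp == g)
    out$best_in_locus[idx[which.min(out$p_mediation[idx])]] <- TRUE
  }
  rownames(out) <- NULL
  out
}
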