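## Expression preprocessing: detection filter, quantile normalization +
## log2, three sample-outlier rules, batch adjustment and residualization
## on covariates plus expression principal components.

#' Filter probes by detection
#'
#' Retains a probe iff the fraction of samples with detection
#' `p <= p_cut` is at least `sample_frac` ("at least 5% of all samples"
#' is inclusive at the boundary).
#'
#' @param E an [expression_matrix()] with `detection_p`.
#' @param detection_p optional detection-p matrix overriding `E$detection_p`.
#' @param p_cut detection p cut-off (default 0.05).
#' @param sample_frac required detected-sample fraction (default 0.05).
#' @return the filtered [expression_matrix()].
#' @export
filter_expressed <- function(E, detection_p = E$detection_p, p_cut = 0.05,
                             sample_frac = 0.05) {
  if (is.null(detection_p)) stop("detection p values are required")
  if (!all(dim(detection_p) == dim(E$values))) {
    stop("detection_p shape does not match the expression matrix")
  }
  frac <- colMeans(detection_p <= p_cut)
  keep <- frac >= sample_frac
  E$values <- E$values[, keep, drop = FALSE]
  E$detection_p <- detection_p[, keep, drop = FALSE]
  E$probes <- E$probes[keep, , drop = FALSE]
  lb <- attr(E, "latent_bio")
  if (!is.null(lb)) attr(E, "latent_bio") <- lb[, keep, drop = FALSE]
  E
}

#' Quantile-normalize across samples, then log2
#'
#' Forces every sample's value distribution onto the across-sample mean
#' quantile vector (ties receive the mean of their quantiles; delegated to
#' limma's quantile normalization on the probes-x-samples orientation),
#' then applies log2.
#'
#' @param E an [expression_matrix()] with positive raw values.
#' @return the normalized, log2-scale [expression_matrix()].
#' @export
quantile_normalize_log2 <- function(E) {
  if (any(E$values <= 0)) stop("quantile normalization + log2 requires positive values")
  norm <- t(limma::normalizeQuantiles(t(E$values), ties = TRUE))
  dimnames(norm) <- dimnames(E$values)
  E$values <- log2(norm)
  E
}

iqr_upper <- function(x) stats::median(x) + 3 * stats::IQR(x)
iqr_flags <- function(x) {
  x < stats::median(x) - 3 * stats::IQR(x) | x > iqr_upper(x)
}

#' Flag sample outliers by three rules
#'
#' Rule 1 (count): a sample's number of expressed probes outside the
#' cohort median +/- 3 IQR. Rule 2 (Euclidean): distance to an artificial
#' individual — the mean expression profile after removing the
#' `ceiling(0.10 n)` samples farthest from the plain mean — larger than
#' median + 3 IQR. Rule 3 (QC Mahalanobis): Mahalanobis distance of the
#' per-sample QC feature vector to the average QC individual larger than
#' median + 3 IQR (a singular QC covariance is ridge-regularized with a
#' warning).
#'
#' @param E an [expression_matrix()] (normalized scale).
#' @param qc_features per-sample QC matrix (defaults to `E$qc_features`).
#' @param detection_p detection-p matrix used for the expressed-probe
#'   count (defaults to `E$detection_p`; when absent, all probes count as
#'   expressed and rule 1 cannot fire).
#' @return a `sample_qc_report` data frame: `sample_id`, `n_expressed`,
#'   `euclid_dist`, `mahalanobis_dist`, `count_outlier`, `euclid_outlier`,
#'   `qc_outlier`, `any_outlier`.
#' @export
flag_sample_outliers <- function(E, qc_features = E$qc_features,
                                 detection_p = E$detection_p) {
  n <- nrow(E$values)
  if (n < 10) stop("sample outlier rules require >= 10 samples")
  n_expressed <- if (!is.null(detection_p)) {
    rowSums(detection_p <= 0.05)
  } else {
    rep(ncol(E$values), n)
  }
  count_outlier <- iqr_flags(n_expressed)

  center0 <- colMeans(E$values)
  d0 <- sqrt(rowSums(sweep(E$values, 2, center0)^2))
  n_trim <- ceiling(0.10 * n)
  keep <- order(d0, decreasing = TRUE)[-seq_len(n_trim)]
  artificial <- colMeans(E$values[keep, , drop = FALSE])
  euclid <- sqrt(rowSums(sweep(E$values, 2, artificial)^2))
  euclid_outlier <- euclid > iqr_upper(euclid)

  if (!is.null(qc_features)) {
    qc <- as.matrix(qc_features)
    mu <- colMeans(qc)
    S <- stats::cov(qc)
    if (rcond(S) < 1e-12) {
      warning("singular QC covariance; ridge-regularizing the diagonal")
      S <- S + diag(1e-6 * sum(diag(S)) / ncol(S), ncol(S))
    }
    maha <- sqrt(stats::mahalanobis(qc, mu, S))
    qc_outlier <- maha > iqr_upper(maha)
  } else {
    maha <- rep(NA_real_, n)
    qc_outlier <- rep(FALSE, n)
  }
  structure(data.frame(sample_id = E$sample_ids, n_expressed = n_expressed,
    euclid_dist = euclid, mahalanobis_dist = maha,
    count_outlier = count_outlier, euclid_outlier = euclid_outlier,
    qc_outlier = qc_outlier,
    any_outlier = count_outlier | euclid_outlier | qc_outlier,
    stringsAsFactors = FALSE), class = c("sample_qc_report", "data.frame"))
}

#' Adjust known batch effects
#'
#' `meanscale`: per probe, subtract each batch's mean and rescale its SD
#' to the pooled residual SD (probe-wise grand mean restored). `eb`: the
#' same location/scale correction, but with the per-(probe, batch)
#' location and log-scale estimates shrunk toward their across-probe batch
#' means by a parametric (normal prior, moment-estimated) empirical-Bayes
#' weight; `prior_var` overrides the moment estimate of the prior variance
#' (0 = infinite prior precision, i.e. every probe gets its batch's
#' average correction).
#'
#' @param E an [expression_matrix()].
#' @param batch batch labels (defaults to `E$batch`).
#' @param mode `"meanscale"` or `"eb"`.
#' @param prior_var optional prior variance override for `eb`.
#' @return the batch-adjusted [expression_matrix()].
#' @export
adjust_batch <- function(E, batch = E$batch, mode = c("meanscale", "eb"),
                         prior_var = NULL) {
  mode <- match.arg(mode)
  if (is.null(batch)) stop("batch labels are required")
  batch <- as.factor(batch)
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("batch with a single sample: ", names(tab)[tab < 2][1])
  }
  V <- E$values
  grand <- colMeans(V)
  levs <- levels(batch)
  bmean <- matrix(0, length(levs), ncol(V))   # batch x probe means
  bsd <- matrix(0, length(levs), ncol(V))
  for (b in seq_along(levs)) {
    rows <- batch == levs[b]
    bmean[b, ] <- colMeans(V[rows, , drop = FALSE])
    bsd[b, ] <- apply(V[rows, , drop = FALSE], 2, stats::sd)
  }
  # pooled within-batch SD per probe
  w <- as.numeric(tab - 1)
  pooled_sd <- sqrt(colSums(bsd^2 * w) / sum(w))
  gamma <- sweep(bmean, 2, grand)             # batch location offsets
  logscale <- log(pmax(bsd, 1e-12)) - matrix(log(pmax(pooled_sd, 1e-12)),
    length(levs), ncol(V), byrow = TRUE)
  if (mode == "eb") {
    for (b in seq_along(levs)) {
      gamma[b, ] <- eb_shrink(gamma[b, ], prior_var)
      logscale[b, ] <- eb_shrink(logscale[b, ], prior_var)
    }
  }
  out <- V
  for (b in seq_along(levs)) {
    rows <- batch == levs[b]
    centered <- sweep(V[rows, , drop = FALSE], 2, grand + gamma[b, ])
    out[rows, ] <- sweep(centered, 2, exp(logscale[b, ]), "/") +
      matrix(grand, sum(rows), ncol(V), byrow = TRUE)
  }
  E$values <- out
  E
}

# Shrink a vector of per-probe batch parameters toward its mean with the
# standard normal-prior weight tau2 / (tau2 + residual var); the moment
# estimate uses the across-probe variance as tau2 + noise and a fixed
# noise share, which is crude but monotone in the right direction.
eb_shrink <- function(est, prior_var = NULL) {
  bar <- mean(est)
  tau2 <- if (is.null(prior_var)) max(stats::var(est), 1e-12) else prior_var
  noise <- stats::var(est) / 4 + 1e-12
  w <- tau2 / (tau2 + noise)
  bar + w * (est - bar)
}

#' Residualize expression on covariates and expression PCs
#'
#' Per probe, returns the OLS residuals after regressing on the covariate
#' set and on the first `n_pcs` principal components of the (already
#' covariate-residualized) expression matrix. Collinear regressors are
#' dropped with a warning. With `n_pcs = 0` and no covariates this is
#' plain probe-wise centering.
#'
#' @param E an [expression_matrix()].
#' @param covariates optional covariate set (see [fit_ols()]).
#' @param n_pcs number of expression PCs to remove (default 5).
#' @return the residualized [expression_matrix()]; the PC scores are
#'   attached as `attr(, "expr_pcs")`.
#' @export
residualize_expression <- function(E, covariates = NULL, n_pcs = 5) {
  V <- E$values
  C <- as_covariate_matrix(covariates, n = nrow(V))
  resid_on <- function(M, Z) {
    X <- cbind(`(Intercept)` = rep(1, nrow(M)), Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      warning("dropping collinear regressor(s): ", paste(dropped, collapse = ", "))
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(X)
    }
    qr.resid(qx, M)
  }
  V1 <- resid_on(V, C)
  pcs <- NULL
  if (n_pcs > 0) {
    pc <- stats::prcomp(V1, center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    pcs <- pc$x[, seq_len(k), drop = FALSE]
    V1 <- resid_on(V1, pcs)
  }
  dimnames(V1) <- dimnames(V)
  E$values <- V1
  attr(E, "expr_pcs") <- pcs
  E
}

#' Run the full expression preprocessing chain
#'
#' Detection filter, quantile normalization + log2, the three sample
#' outlier rules (flagged samples removed and recorded), batch
#' adjustment, and residualization on covariates plus expression PCs.
#'
#' @param E a raw-intensity [expression_matrix()].
#' @param covariates covariate set for residualization.
#' @param cfg a [default_config()] (detection thresholds, number of PCs).
#' @param batch_mode `"meanscale"` or `"eb"`.
#' @return the analysis-ready [expression_matrix()]; the QC report and
#'   removal ledger are attached as `attr(, "qc_report")` and
#'   `attr(, "removed_samples")`.
#' @export
prepare_expression <- function(E, covariates = NULL, cfg = default_config(),
                               batch_mode = "meanscale") {
  E <- filter_expressed(E, p_cut = cfg$detection_p_cut,
    sample_frac = cfg$detection_sample_frac)
  E <- quantile_normalize_log2(E)
  qc <- flag_sample_outliers(E)
  removed <- qc$sample_id[qc$any_outlier]
  if (length(removed) > 0) {
    keep <- setdiff(E$sample_ids, removed)
    E <- subset_samples(E, keep)
    if (!is.null(attr(E, "latent_bio"))) {
      attr(E, "latent_bio") <- attr(E, "latent_bio")[match(keep, rownames(attr(E, "latent_bio"))), , drop = FALSE]
    }
  }
  if (!is.null(E$batch)) E <- adjust_batch(E, mode = batch_mode)
  Csub <- if (is.null(covariates)) NULL else {
    as_covariate_matrix(covariates)[match(E$sample_ids, covariates$sample_ids), , drop = FALSE]
  }
  E <- residualize_expression(E, Csub, n_pcs = cfg$n_expr_pcs)
  attr(E, "qc_report") <- qc
  attr(E, "removed_samples") <- data.frame(sample_id = removed,
    rule = vapply(removed, function(s) {
      r <- qc[qc$sample_id == s, ]
      paste(c("count", "euclid", "qc")[c(r$count_outlier, r$euclid_outlier, r$qc_outlier)],
        collapse = "+")
    }, character(1)))
  E
}
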