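## Multiplicity control for correlated multi-trait scans: an empirical
## permutation null with q-values for the mQTL layer, and layer-specific
## Benjamini-Hochberg thresholds (with permutation confirmation) for the
## eQTL layers.

#' Convert scan t statistics into permutation-null statistics
#'
#' `"neglog10p"`: `-log10` of the two-sided p value (larger = more
#' extreme). `"signed_z"`: the signed normal quantile of the two-sided p,
#' optionally multiplied by a per-test orientation (e.g. the discovery
#' effect direction, which makes replication statistics one-sided).
#'
#' @param tval t statistics.
#' @param df residual degrees of freedom (recycled).
#' @param kind `"neglog10p"` or `"signed_z"`.
#' @param orientation optional sign vector for `"signed_z"`.
#' @return numeric statistic vector.
#' @export
scan_statistic <- function(tval, df, kind, orientation = NULL) {
  p <- 2 * stats::pt(-abs(tval), pmax(df, 1))
  if (kind == "neglog10p") {
    -log10(pmax(p, .Machine$double.xmin))
  } else {
    z <- stats::qnorm(pmax(p / 2, .Machine$double.xmin), lower.tail = FALSE) * sign(tval)
    if (!is.null(orientation)) z <- z * orientation
    z
  }
}

#' Permutation null for a genotype-phenotype scan
#'
#' Breaks the SNP-phenotype links by permuting the sample index of the
#' whole phenotype block against the genotypes; the covariates stay
#' attached to the genotypes, so the null is covariate-adjusted
#' exchangeability. LD among SNPs and the correlation among phenotypes are
#' preserved. For every permutation the full test grid is recomputed and
#' the chosen statistic collected.
#'
#' @param G a [genotype_matrix()] (or plain dose matrix).
#' @param panel a [metabolite_panel()] (or plain trait matrix).
#' @param covariates optional covariate set.
#' @param n_perm number of permutations (default 1000).
#' @param statistic_kind `"neglog10p"` (two-sided) or `"signed_z"`.
#' @param seed RNG seed for the permutation stream.
#' @param orientation optional per-test sign vector applied to signed-z
#'   statistics (e.g. the discovery effect direction, making replication
#'   statistics one-sided).
#' @return an object of class `permutation_null`: list with `layer`,
#'   `n_perm`, `statistic_kind`, `null_stats` (n_perm x n_tests matrix,
#'   tests in column-major grid order: SNPs fastest), `seed`.
#' @export
permute_phenotype_links <- function(G, panel, covariates = NULL,
                                    n_perm = 1000, statistic_kind = c("neglog10p", "signed_z"),
                                    seed = 1L, orientation = NULL) {
  statistic_kind <- match.arg(statistic_kind)
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- if (inherits(G, "genotype_matrix")) G$doses else as.matrix(G)
  Y <- if (inherits(panel, "metabolite_panel")) panel$values else as.matrix(panel)
  C <- as_covariate_matrix(covariates, n = nrow(X))
  set.seed(seed)
  n <- nrow(X)
  null_stats <- matrix(NA_real_, n_perm, ncol(X) * ncol(Y))
  for (r in seq_len(n_perm)) {
    idx <- sample.int(n)
    core <- scan_core(X, Y[idx, , drop = FALSE], C)
    df <- rep(core$df, each = ncol(X))
    null_stats[r, ] <- scan_statistic(as.vector(core$t), df, statistic_kind,
      orientation)
  }
  structure(list(layer = "mqtl", n_perm = n_perm,
    statistic_kind = statistic_kind, null_stats = null_stats, seed = seed),
    class = "permutation_null")
}

#' Empirical q-values from a permutation null
#'
#' `FDRhat(t) = mean over permutations of #\{null >= t\} / max(1,
#' #\{observed >= t\})`, evaluated at the observed statistic values;
#' `q(s_i)` is the minimum of `FDRhat(t)` over thresholds `t <= s_i`
#' (i.e. over all rejection regions containing `s_i`), capped at 1.
#'
#' @param observed vector of observed statistics (larger = more extreme).
#' @param null a `permutation_null` or a matrix/vector of null statistics
#'   (rows = permutations when a matrix).
#' @param n_perm number of permutations when `null` is a plain vector.
#' @return q-values aligned with `observed`.
#' @export
empirical_qvalues <- function(observed, null, n_perm = NULL) {
  if (inherits(null, "permutation_null")) {
    n_perm <- null$n_perm
    pooled <- as.vector(null$null_stats)
  } else if (is.matrix(null)) {
    n_perm <- nrow(null)
    pooled <- as.vector(null)
  } else {
    if (is.null(n_perm)) stop("n_perm required when null is a plain vector")
    pooled <- as.vector(null)
  }
  pooled <- pooled[is.finite(pooled)]
  ord <- order(observed, decreasing = TRUE)
  s <- observed[ord]
  ns <- sort(pooled)
  # #{null >= t} = N - #{null < t}, via the sorted null vector
  null_ge <- length(ns) - findInterval(s, ns, left.open = TRUE)
  fdr <- (null_ge / n_perm) / pmax(1, seq_along(s))
  q <- rev(cummin(rev(pmin(fdr, 1))))
  out <- numeric(length(observed))
  out[ord] <- q
  out
}

#' Benjamini-Hochberg q-values
#' @param pvals p values in (0, 1].
#' @return BH-adjusted q-values.
#' @export
bh_qvalues <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Layer-specific Benjamini-Hochberg thresholds
#'
#' Runs the step-up BH procedure separately within the cis and the trans
#' layer and returns each layer's significance threshold: the largest p
#' value among that layer's rejected tests (0 when nothing is rejected).
#'
#' @param p_cis p values of the cis-layer tests.
#' @param p_trans p values of the trans-layer tests.
#' @param alpha FDR level (default 0.05).
#' @return list with `cis` and `trans` thresholds and rejection counts.
#' @export
bh_layer_thresholds <- function(p_cis, p_trans, alpha = 0.05) {
  thr <- function(p) {
    if (length(p) == 0) return(list(threshold = 0, n_reject = 0L))
    sp <- sort(p)
    crit <- seq_along(sp) / length(sp) * alpha
    pass <- which(sp <= crit)
    if (length(pass) == 0) return(list(threshold = 0, n_reject = 0L))
    k <- max(pass)
    list(threshold = sp[k], n_reject = k)
  }
  ci <- thr(p_cis); tr <- thr(p_trans)
  list(cis = ci$threshold, trans = tr$threshold,
    n_reject_cis = ci$n_reject, n_reject_trans = tr$n_reject)
}

#' Confirm BH thresholds by permutation
#'
#' Estimates the empirical false-discovery proportion at the layer-wise BH
#' thresholds by permuting the expression block against the genotypes
#' (`n_perm` times, default 100) and comparing the average null rejection
#' count with the observed rejection count.
#'
#' @param X dose matrix of the scanned SNPs (samples x SNPs).
#' @param Y expression matrix (samples x probes), fully preprocessed.
#' @param cis_flags logical vector over the test grid (column-major, SNPs
#'   fastest) marking cis tests.
#' @param covariates optional covariate set.
#' @param alpha FDR level.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @return list with the observed thresholds, observed rejection counts
#'   and the permutation-estimated empirical FDR per layer.
#' @export
verify_bh_with_permutations <- function(X, Y, cis_flags, covariates = NULL,
                                        alpha = 0.05, n_perm = 100, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  C <- as_covariate_matrix(covariates, n = nrow(X))
  core <- scan_core(X, Y, C)
  p_obs <- 2 * stats::pt(-abs(as.vector(core$t)), pmax(rep(core$df, each = ncol(X)), 1))
  thr <- bh_layer_thresholds(p_obs[cis_flags], p_obs[!cis_flags], alpha)
  obs_cis <- sum(p_obs[cis_flags] <= thr$cis & thr$cis > 0)
  obs_trans <- sum(p_obs[!cis_flags] <= thr$trans & thr$trans > 0)
  set.seed(seed)
  null_cis <- null_trans <- numeric(n_perm)
  n <- nrow(X)
  for (r in seq_len(n_perm)) {
    idx <- sample.int(n)
    cr <- scan_core(X, Y[idx, , drop = FALSE], C)
    pp <- 2 * stats::pt(-abs(as.vector(cr$t)), pmax(rep(cr$df, each = ncol(X)), 1))
    null_cis[r] <- sum(pp[cis_flags] <= thr$cis)
    null_trans[r] <- sum(pp[!cis_flags] <= thr$trans)
  }
  list(nominal = alpha,
    threshold_cis = thr$cis, threshold_trans = thr$trans,
    n_reject_cis = obs_cis, n_reject_trans = obs_trans,
    empirical_fdr_cis = mean(null_cis) / max(1, obs_cis),
    empirical_fdr_trans = mean(null_trans) / max(1, obs_trans),
    null_mean_cis = mean(null_cis), null_mean_trans = mean(null_trans),
    seed = seed)
}
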