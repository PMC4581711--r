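## Discovery mQTL scan, LD pruning of lead SNPs, locus assignment, proxy
## search in the replication panel, and direction-consistent replication.

#' Genome-wide SNP-metabolite scan
#'
#' One covariate-adjusted OLS per (SNP, quantity) pair. The full p table
#' is retained (the permutation FDR machinery needs the complete grid);
#' pairs below the liberal reporting cut-off form the top list carried to
#' replication.
#'
#' @param G a [genotype_matrix()].
#' @param panel a prepared (masked-stage) [metabolite_panel()]; a plain
#'   matrix is also accepted.
#' @param covariates covariate set.
#' @param p_report discovery reporting cut-off (default 1e-7).
#' @return list with `scan` (all association records, layer `"mqtl"`),
#'   `top` (records with `p < p_report`, ordered by p) and
#'   `lambda` (genomic inflation factor of the scan).
#' @export
run_mqtl_scan <- function(G, panel, covariates = NULL, p_report = 1e-7) {
  X <- if (inherits(G, "genotype_matrix")) G$doses else as.matrix(G)
  Y <- if (inherits(panel, "metabolite_panel")) panel$values else as.matrix(panel)
  scan <- assoc_scan(X, Y, covariates, layer = "mqtl")
  ok <- !is.na(scan$p)
  top <- scan[ok & scan$p < p_report, , drop = FALSE]
  top <- top[order(top$p), , drop = FALSE]
  list(scan = scan, top = top, lambda = genomic_lambda(scan$p[ok]))
}

#' Pairwise LD as squared dose correlation
#'
#' @param G a [genotype_matrix()] (or dose matrix).
#' @param snp_a,snp_b SNP ids (or column indices).
#' @return squared Pearson correlation of the two dose vectors on their
#'   complete cases.
#' @export
ld_r2 <- function(G, snp_a, snp_b) {
  X <- if (inherits(G, "genotype_matrix")) G$doses else as.matrix(G)
  a <- X[, snp_a]; b <- X[, snp_b]
  ok <- is.finite(a) & is.finite(b)
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
    stop("monomorphic SNP in LD computation")
  }
  stats::cor(a[ok], b[ok])^2
}

#' Greedy LD pruning of the top list
#'
#' Each SNP is ranked by its minimal p over all quantities. Greedily: keep
#' the best-ranked remaining SNP, discard every remaining SNP with LD
#' `r2 >= r2_max` to it, repeat. Retained records keep all their
#' (SNP, quantity) rows.
#'
#' @param top association records from [run_mqtl_scan()] (`$top`).
#' @param G the discovery [genotype_matrix()] (LD source).
#' @param r2_max pruning threshold (default 0.3; retained pairs satisfy
#'   `r2 < r2_max`).
#' @return an object of class `lead_snp_set`: list with `records` (pruned
#'   rows, ascending discovery p), `lead_snps` (data frame: `snp_id`,
#'   `min_p`, `chrom`, `pos`, pruning order) and `r2_max`.
#' @export
prune_lead_snps <- function(top, G, r2_max = 0.3) {
  if (nrow(top) == 0) stop("empty top list")
  X <- G$doses
  minp <- tapply(top$p, top$x_id, min)
  cand <- names(sort(minp))             # ascending minimal p
  kept <- character(0)
  remaining <- cand
  while (length(remaining) > 0) {
    best <- remaining[1]
    kept <- c(kept, best)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      r2 <- vapply(remaining, function(s) ld_r2(G, best, s), numeric(1))
      remaining <- remaining[r2 < r2_max]
    }
  }
  rec <- top[top$x_id %in% kept, , drop = FALSE]
  rec <- rec[order(rec$p), , drop = FALSE]
  meta <- G$snps[match(kept, G$snps$snp_id), , drop = FALSE]
  leads <- data.frame(snp_id = kept, min_p = as.numeric(minp[kept]),
    chrom = meta$chrom, pos = meta$pos, rank = seq_along(kept),
    stringsAsFactors = FALSE)
  structure(list(records = rec, lead_snps = leads, r2_max = r2_max),
    class = "lead_snp_set")
}

#' Merge lead SNPs into genomic loci
#'
#' Single-linkage: lead SNPs on the same chromosome are chained into one
#' locus whenever consecutive positions are within `merge_bp`; locus ids
#' are ordered along the genome.
#'
#' @param leads a `lead_snp_set`.
#' @param merge_bp merge distance (default 1 Mb).
#' @return the `lead_snp_set` with a `locus_id` column added to
#'   `lead_snps` and `records`.
#' @export
assign_loci <- function(leads, merge_bp = 1000000) {
  df <- leads$lead_snps
  ord <- order(suppressWarnings(as.numeric(df$chrom)), df$chrom, df$pos)
  df <- df[ord, , drop = FALSE]
  locus <- integer(nrow(df))
  cur <- 0L
  for (i in seq_len(nrow(df))) {
    if (i == 1 || df$chrom[i] != df$chrom[i - 1] ||
        df$pos[i] - df$pos[i - 1] > merge_bp) {
      cur <- cur + 1L
    }
    locus[i] <- cur
  }
  df$locus_id <- sprintf("L%02d", locus)
  leads$lead_snps <- df[order(df$rank), , drop = FALSE]
  leads$records$locus_id <-
    leads$lead_snps$locus_id[match(leads$records$x_id, leads$lead_snps$snp_id)]
  leads
}

#' Find replication proxies for lead SNPs
#'
#' For every lead SNP: candidate proxies are the replication-panel SNPs
#' within `window_bp` of the lead with imputation info above `info_min`;
#' LD between lead and candidate is computed in the discovery cohort
#' (where both exist), and the best candidate with `r2 > r2_min` wins. A
#' lead present in the replication panel is its own proxy (r2 = 1).
#'
#' @param leads a `lead_snp_set`.
#' @param G_disc discovery [genotype_matrix()] (LD source).
#' @param G_rep replication [genotype_matrix()] (availability + info).
#' @param window_bp search window (default +/-50 kb).
#' @param r2_min proxy LD threshold (strict, default 0.8).
#' @param info_min imputation-info threshold (strict, default 0.3).
#' @return data frame of proxy pairs (`lead_snp_id`, `proxy_snp_id`, `r2`,
#'   `distance`, `proxy_info`); leads without a qualifying proxy appear
#'   with `proxy_snp_id = NA` (unreplicable).
#' @export
find_proxies <- function(leads, G_disc, G_rep, window_bp = 50000,
                         r2_min = 0.8, info_min = 0.3) {
  out <- lapply(leads$lead_snps$snp_id, function(s) {
    meta <- G_disc$snps[match(s, G_disc$snps$snp_id), ]
    if (s %in% G_rep$snps$snp_id) {
      info <- G_rep$snps$info[match(s, G_rep$snps$snp_id)]
      if (info > info_min) {
        return(data.frame(lead_snp_id = s, proxy_snp_id = s, r2 = 1,
          distance = 0L, proxy_info = info, stringsAsFactors = FALSE))
      }
    }
    cand <- G_rep$snps[G_rep$snps$chrom == meta$chrom &
      abs(G_rep$snps$pos - meta$pos) <= window_bp &
      G_rep$snps$info > info_min &
      G_rep$snps$snp_id != s &
      G_rep$snps$snp_id %in% G_disc$snps$snp_id, , drop = FALSE]
    if (nrow(cand) > 0) {
      r2 <- vapply(cand$snp_id, function(cs) {
        tryCatch(ld_r2(G_disc, s, cs), error = function(e) NA_real_)
      }, numeric(1))
      ok <- which(!is.na(r2) & r2 > r2_min)
      if (length(ok) > 0) {
        j <- ok[which.max(r2[ok])]
        return(data.frame(lead_snp_id = s, proxy_snp_id = cand$snp_id[j],
          r2 = r2[j], distance = abs(cand$pos[j] - meta$pos),
          proxy_info = cand$info[j], stringsAsFactors = FALSE))
      }
    }
    data.frame(lead_snp_id = s, proxy_snp_id = NA_character_, r2 = NA_real_,
      distance = NA_integer_, proxy_info = NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Replicate discovery pairs in the second cohort
#'
#' Each discovery (lead SNP, quantity) pair is re-tested in the
#' replication cohort through its proxy. Effect directions are compared
#' after orienting the proxy by the sign of its dose correlation with the
#' lead in the discovery cohort; pairs whose orientation is indeterminate
#' (|r| < 0.05) are flagged unorientable and excluded with a warning.
#' Replication q-values come from a signed-z permutation null oriented by
#' the discovery direction (one-sided); a pair is replicated when its
#' direction is consistent and `q <= fdr`.
#'
#' @param top_records pruned discovery records (a `lead_snp_set`'s
#'   `records`).
#' @param proxies proxy table from [find_proxies()].
#' @param G_disc,G_rep discovery and replication [genotype_matrix()].
#' @param panel_rep prepared replication [metabolite_panel()].
#' @param covariates_rep replication covariate set (fewer covariates than
#'   discovery: age and sex).
#' @param fdr FDR level (default 0.05).
#' @param n_perm permutations for the replication null (default 1000).
#' @param seed RNG seed.
#' @return data frame: discovery beta/se/p, replication beta/se/p/q (on
#'   the lead-SNP orientation), `orientation`, `direction_consistent`,
#'   `replicated`; unreplicable or unorientable pairs carry NA statistics.
#' @export
replicate_associations <- function(top_records, proxies, G_disc, G_rep,
                                   panel_rep, covariates_rep = NULL,
                                   fdr = 0.05, n_perm = 1000, seed = 2L) {
  if (nrow(top_records) == 0) {
    return(data.frame(lead_snp_id = character(), metabolite = character(),
      locus_id = character(), proxy_snp_id = character(),
      beta_disc = numeric(), se_disc = numeric(), p_disc = numeric(),
      beta_rep = numeric(), se_rep = numeric(), p_rep = numeric(),
      q_rep = numeric(), n_rep = integer(), orientation = numeric(),
      direction_consistent = logical(), replicated = logical(),
      stringsAsFactors = FALSE))
  }
  prox <- proxies$proxy_snp_id[match(top_records$x_id, proxies$lead_snp_id)]
  res <- data.frame(
    lead_snp_id = top_records$x_id,
    metabolite = top_records$y_id,
    locus_id = if (!is.null(top_records$locus_id)) top_records$locus_id else
      rep(NA_character_, nrow(top_records)),
    proxy_snp_id = prox,
    beta_disc = top_records$beta, se_disc = top_records$se, p_disc = top_records$p,
    beta_rep = NA_real_, se_rep = NA_real_, p_rep = NA_real_, q_rep = NA_real_,
    n_rep = NA_integer_, orientation = NA_real_,
    direction_consistent = NA, replicated = NA,
    stringsAsFactors = FALSE)
  testable <- which(!is.na(prox) & res$metabolite %in% colnames(panel_rep$values))
  if (length(testable) == 0) return(res)

  used <- unique(prox[testable])
  Xrep <- G_rep$doses[, used, drop = FALSE]
  Yrep <- panel_rep$values
  scan <- assoc_scan(Xrep, Yrep, covariates_rep, layer = "mqtl_rep")
  key <- paste(scan$x_id, scan$y_id)
  hit <- match(paste(prox[testable], res$metabolite[testable]), key)

  orient <- vapply(testable, function(i) {
    a <- G_disc$doses[, res$lead_snp_id[i]]
    b <- G_disc$doses[, res$proxy_snp_id[i]]
    stats::cor(a, b)
  }, numeric(1))
  unorientable <- abs(orient) < 0.05
  if (any(unorientable)) {
    warning(sum(unorientable), " pair(s) unorientable (|r| < 0.05); excluded")
  }

  res$beta_rep[testable] <- scan$beta[hit] * sign(orient)
  res$se_rep[testable] <- scan$se[hit]
  res$p_rep[testable] <- scan$p[hit]
  res$n_rep[testable] <- scan$n[hit]
  res$orientation[testable] <- sign(orient)
  res$direction_consistent[testable] <-
    sign(res$beta_rep[testable]) == sign(res$beta_disc[testable])

  # one-sided signed-z q-values: orientation = discovery direction,
  # statistic grid = used proxies x replication panel
  disc_dir <- matrix(0, length(used), ncol(Yrep),
    dimnames = list(used, colnames(Yrep)))
  for (i in testable) {
    disc_dir[prox[i], res$metabolite[i]] <- sign(res$beta_disc[i]) * sign(orient[match(i, testable)])
  }
  obs_z <- scan_statistic(scan$t, scan$df, "signed_z") * as.vector(disc_dir)
  nullz <- permute_phenotype_links(Xrep, Yrep, covariates_rep, n_perm = n_perm,
    statistic_kind = "signed_z", seed = seed, orientation = as.vector(disc_dir))
  grid_in_use <- as.vector(disc_dir) != 0
  qgrid <- rep(NA_real_, length(obs_z))
  qgrid[grid_in_use] <- empirical_qvalues(obs_z[grid_in_use],
    nullz$null_stats[, grid_in_use, drop = FALSE])
  res$q_rep[testable] <- qgrid[hit]

  res$replicated[testable] <- res$direction_consistent[testable] &
    !is.na(res$q_rep[testable]) & res$q_rep[testable] <= fdr
  if (any(unorientable)) {
    bad <- testable[unorientable]
    res[bad, c("beta_rep", "se_rep", "p_rep", "q_rep", "orientation")] <- NA
    res$direction_consistent[bad] <- NA
    res$replicated[bad] <- NA
  }
  res
}
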