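## End-to-end orchestration: preprocessing, the discovery mQTL scan with
## permutation FDR, pruning and replication, eQTL and expression-metabolite
## integration, triangle discovery with its permutation/Poisson null, the
## causal module, and network assembly.

#' Restrict a covariate table to selected columns (and samples)
#'
#' @param C a [covariate_table()].
#' @param cols covariate names to keep (missing names are ignored).
#' @param samples optional sample ids to subset/reorder to.
#' @return a [covariate_table()].
#' @export
subset_covariates <- function(C, cols, samples = NULL) {
  stopifnot(inherits(C, "covariate_table"))
  d <- C$data[, intersect(cols, names(C$data)), drop = FALSE]
  if (!is.null(samples)) d <- d[match(samples, C$sample_ids), , drop = FALSE]
  covariate_table(d)
}

# Metabolites significant at each SNP (the triangle candidate map)
snp_metab_map <- function(records) {
  split(records$y_id, records$x_id)
}

#' Candidate grid for the expression-metabolite layer
#'
#' Pairs each eQTL-significant probe with the metabolites that are
#' mQTL-associated at its SNP(s) — the grid the triangle search closes
#' over.
#'
#' @param eqtl_records eQTL association records with `significant`.
#' @param mqtl_records validated mQTL records.
#' @return data frame with `probe_id` and `metabolite`.
#' @export
candidate_pairs <- function(eqtl_records, mqtl_records) {
  eq <- eqtl_records[isTRUE_vec(eqtl_records$significant), , drop = FALSE]
  mp <- snp_metab_map(mqtl_records)
  out <- lapply(seq_len(nrow(eq)), function(i) {
    ms <- mp[[eq$x_id[i]]]
    if (is.null(ms)) return(NULL)
    data.frame(probe_id = eq$y_id[i], metabolite = ms, stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, out))
  if (is.null(out)) data.frame(probe_id = character(), metabolite = character()) else out
}

#' Expression-metabolite tests on a restricted candidate-pair set
#'
#' Runs [run_expr_metab_scan()] over the pairs' probes and metabolites,
#' keeps only the candidate pairs, and applies BH within that set (or a
#' frozen p threshold inside the triangle permutation null).
#'
#' @param pairs candidate pairs from [candidate_pairs()].
#' @param E,panel,covariates,fdr see [run_expr_metab_scan()].
#' @param p_threshold optional frozen significance threshold.
#' @return list with `records` and `threshold`.
#' @export
exprmet_on_pairs <- function(pairs, E, panel, covariates = NULL, fdr = 0.05,
                             p_threshold = NULL) {
  if (nrow(pairs) == 0) return(list(records = empty_records("expr_metab"), threshold = 0))
  probes <- unique(pairs$probe_id)
  metabs <- unique(pairs$metabolite)
  full <- run_expr_metab_scan(probes, metabs, E, panel, covariates, fdr)
  rec <- full$records
  keep <- paste(rec$x_id, rec$y_id) %in% paste(pairs$probe_id, pairs$metabolite)
  rec <- rec[keep, , drop = FALSE]
  if (is.null(p_threshold)) {
    rec$q <- bh_qvalues(rec$p)
    rec$significant <- !is.na(rec$q) & rec$q <= fdr
    thr <- if (any(rec$significant)) max(rec$p[rec$significant]) else 0
  } else {
    rec$significant <- !is.na(rec$p) & rec$p <= p_threshold & p_threshold > 0
    thr <- p_threshold
  }
  list(records = rec, threshold = thr)
}

#' Run the full integrative pipeline on a simulated (or loaded) study
#'
#' Executes: metabolite preparation (derive, dichotomize, arsinh, outlier
#' mask) and expression preparation (detection filter, quantile
#' normalization, sample QC, batch adjustment, residualization) for both
#' cohorts; the discovery mQTL scan with genomic-inflation diagnostic and
#' permutation-based q-values; greedy LD pruning, locus assignment, proxy
#' search and direction-consistent replication; the cis/trans eQTL scan of
#' the lead SNPs with layer-specific BH thresholds (permutation-checked);
#' the expression-metabolite layer on the triangle candidate grid;
#' association-triangle discovery (strict and exhaustive) with the
#' permutation/Poisson null; the adapted-MR and mediation tests per
#' strict triangle; and the network export tables.
#'
#' @param study bundle from [simulate_study()] (or equivalently structured
#'   loaded data).
#' @param cfg a [default_config()].
#' @return a list of stage results (see the pipeline vignette).
#' @export
run_pipeline <- function(study, cfg = default_config()) {
  set.seed(cfg$seed)
  ## -- preprocessing ------------------------------------------------------
  M_d <- prepare_metabolites(study$discovery$metabolites,
    frac_threshold = cfg$lod_frac, k = cfg$outlier_k)
  M_r <- prepare_metabolites(study$replication$metabolites,
    frac_threshold = cfg$lod_frac, k = cfg$outlier_k)
  E_d <- prepare_expression(study$discovery$expression,
    covariates = subset_covariates(study$discovery$covariates, c("age", "sex")),
    cfg = cfg)
  G_d <- study$discovery$genotypes
  C_d <- study$discovery$covariates
  G_r <- study$replication$genotypes
  C_r <- study$replication$covariates

  ## -- discovery mQTL scan + permutation FDR ------------------------------
  hm <- harmonize_samples(genotypes = G_d, metabolites = M_d, covariates = C_d)
  scan <- run_mqtl_scan(hm$genotypes, hm$metabolites, hm$covariates,
    p_report = cfg$p_report)
  obs_stat <- scan_statistic(scan$scan$t, scan$scan$df, "neglog10p")
  nullobj <- permute_phenotype_links(hm$genotypes, hm$metabolites,
    hm$covariates, n_perm = cfg$n_perm_mqtl, statistic_kind = "neglog10p",
    seed = cfg$seed + 101L)
  qvals <- empirical_qvalues(obs_stat, nullobj)
  scan$scan$q <- qvals
  scan$top$q <- qvals[match(paste(scan$top$x_id, scan$top$y_id),
    paste(scan$scan$x_id, scan$scan$y_id))]
  if (nrow(scan$top) > 0) {
    leads <- prune_lead_snps(scan$top, hm$genotypes, r2_max = cfg$prune_r2)
    leads <- assign_loci(leads, merge_bp = cfg$locus_merge_bp)
  } else {
    leads <- structure(list(records = cbind(scan$top, locus_id = character(0)),
      lead_snps = data.frame(snp_id = character(), min_p = numeric(),
        chrom = character(), pos = integer(), rank = integer(),
        locus_id = character(), stringsAsFactors = FALSE),
      r2_max = cfg$prune_r2), class = "lead_snp_set")
  }
  validated <- leads$records[!is.na(leads$records$q) & leads$records$q <= cfg$fdr, ,
    drop = FALSE]
  mqtl_p_threshold <- if (nrow(validated) > 0) {
    min(cfg$p_report, max(validated$p))
  } else 0

  ## -- replication --------------------------------------------------------
  proxies <- find_proxies(leads, G_d, G_r, window_bp = cfg$proxy_window,
    r2_min = cfg$proxy_r2, info_min = cfg$info_min)
  hr <- harmonize_samples(genotypes = G_r, metabolites = M_r, covariates = C_r)
  replication <- replicate_associations(leads$records, proxies,
    G_d, hr$genotypes, hr$metabolites,
    subset_covariates(hr$covariates, c("age", "sex")),
    fdr = cfg$fdr, n_perm = cfg$n_perm_mqtl, seed = cfg$seed + 202L)

  ## -- eQTL scan of lead SNPs ---------------------------------------------
  he <- harmonize_samples(genotypes = G_d, expression = E_d, covariates = C_d)
  eqtl <- run_eqtl_scan(leads, he$genotypes, he$expression,
    subset_covariates(he$covariates, c("pc1", "pc2", "pc3")),
    fdr = cfg$fdr, cis_window = cfg$cis_window)
  lead_idx <- intersect(leads$lead_snps$snp_id, colnames(he$genotypes$doses))
  bh_check <- if (length(lead_idx) > 0) {
    verify_bh_with_permutations(
      he$genotypes$doses[, lead_idx, drop = FALSE], he$expression$values,
      eqtl$records$layer == "eqtl_cis",
      subset_covariates(he$covariates, c("pc1", "pc2", "pc3")),
      alpha = cfg$fdr, n_perm = cfg$n_perm_bh_check, seed = cfg$seed + 303L)
  } else NULL

  ## -- expression-metabolite layer on the candidate grid -------------------
  hc <- harmonize_samples(genotypes = G_d, expression = E_d,
    metabolites = M_d, covariates = C_d)
  pairs <- candidate_pairs(eqtl$records, validated)
  exprmet <- exprmet_on_pairs(pairs, hc$expression, hc$metabolites,
    subset_covariates(hc$covariates, c("age", "sex")), fdr = cfg$fdr)

  ## -- triangles + permutation/Poisson null --------------------------------
  tri_strict <- build_triangles(validated, eqtl$records, exprmet$records,
    mode = "strict")
  tri_exh <- build_triangles(validated, eqtl$records, exprmet$records,
    mode = "exhaustive")
  thresholds <- list(mqtl_p = mqtl_p_threshold,
    eqtl_cis = eqtl$thresholds$cis, eqtl_trans = eqtl$thresholds$trans,
    exprmet_p = exprmet$threshold)
  tri_null <- triangle_permutation_null(hc, cfg, thresholds,
    observed_leads = if (cfg$freeze_leads) leads else NULL,
    n_perm = cfg$n_perm_triangle, seed = cfg$seed + 404L)
  poisson_p <- poisson_tail_p(nrow(tri_strict), tri_null$lambda_hat)

  ## -- causal module -------------------------------------------------------
  causal <- summarize_causal(tri_strict, hc$genotypes, hc$expression,
    hc$metabolites, hc$covariates, locus_map = leads$lead_snps)

  ## -- network -------------------------------------------------------------
  network <- build_network(validated, eqtl$records, exprmet$records,
    hc$metabolites, hc$expression, triangles = tri_exh,
    lead_loci = leads$lead_snps)

  structure(list(config = cfg,
    metabolites_discovery = M_d, expression_discovery = E_d,
    lambda = scan$lambda, scan = scan$scan, top = scan$top,
    mqtl_null = nullobj, leads = leads, validated = validated,
    mqtl_p_threshold = mqtl_p_threshold,
    proxies = proxies, replication = replication,
    eqtl = eqtl, bh_check = bh_check,
    candidate_pairs = pairs, exprmet = exprmet,
    triangles = tri_strict, triangles_exhaustive = tri_exh,
    triangle_null = tri_null, poisson_p = poisson_p,
    causal = causal, network = network,
    n_samples = list(mqtl = hm$n, replication = hr$n, eqtl = he$n,
      integrated = hc$n)), class = "triqtl_pipeline")
}

#' @export
print.triqtl_pipeline <- function(x, ...) {
  cat("lambda:", round(x$lambda, 4), "\n")
  cat("top:", nrow(x$top), "leads:", nrow(x$leads$lead_snps),
    "loci:", length(unique(x$leads$lead_snps$locus_id)), "\n")
  tst <- x$replication[!is.na(x$replication$direction_consistent), ,
    drop = FALSE]
  cat("replication:", sum(tst$replicated, na.rm = TRUE), "of", nrow(tst),
    " dir consistent:",
    if (nrow(tst) > 0) round(100 * mean(tst$direction_consistent), 1) else NA,
    "\n")
  eq <- x$eqtl$records[isTRUE_vec(x$eqtl$records$significant), , drop = FALSE]
  cat("eqtl cis:", sum(eq$layer == "eqtl_cis"),
    "trans:", sum(eq$layer == "eqtl_trans"), "\n")
  cat("triangles:", nrow(x$triangles),
    "null mean:", x$triangle_null$lambda_hat,
    "poisson:", signif(x$poisson_p, 4), "\n")
  if (nrow(x$causal) > 0) {
    print(x$causal[, c("snp_id", "probe_id", "metabolite", "beta_mr",
      "p_mr", "delta", "p_mediation")], digits = 3)
  }
  invisible(x)
}

#' Permutation null for the association-triangle count
#'
#' Per permutation the sample assignment of the expression block and
#' (independently) of the metabolite block is shuffled against the
#' genotype/covariate block, destroying all three association layers'
#' dependence while preserving within-block correlation; the pipeline
#' (scan, pruning, locus assignment, eQTL, expression-metabolite,
#' triangle closure, strict mode) is rerun with the observed run's frozen
#' thresholds, and the triangle count collected. The null mean
#' `lambda_hat` feeds the Poisson tail test.
#'
#' @param hc harmonized bundle (list with `genotypes`, `expression`,
#'   `metabolites`, `covariates` on a common sample set).
#' @param cfg a [default_config()].
#' @param thresholds frozen thresholds: `mqtl_p`, `eqtl_cis`,
#'   `eqtl_trans`, `exprmet_p`.
#' @param observed_leads optionally freeze the observed `lead_snp_set`
#'   instead of re-pruning per permutation.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @return an object of class `triangle_null`: list with `n_perm`,
#'   `counts`, `lambda_hat`, `seed`.
#' @export
triangle_permutation_null <- function(hc, cfg, thresholds,
                                      observed_leads = NULL,
                                      n_perm = 100, seed = 1L) {
  set.seed(seed)
  n <- hc$n %||% nrow(hc$genotypes$doses)
  counts <- integer(n_perm)
  C_full <- hc$covariates
  C_age_sex <- subset_covariates(C_full, c("age", "sex"))
  C_pcs <- subset_covariates(C_full, c("pc1", "pc2", "pc3"))
  for (r in seq_len(n_perm)) {
    idxE <- sample.int(n)
    idxM <- sample.int(n)
    counts[r] <- count_triangles_permuted(hc, cfg, thresholds, idxE, idxM,
      observed_leads, C_full, C_age_sex, C_pcs)
  }
  structure(list(n_perm = n_perm, counts = counts,
    lambda_hat = mean(counts), seed = seed), class = "triangle_null")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

count_triangles_permuted <- function(hc, cfg, thresholds, idxE, idxM,
                                     observed_leads, C_full, C_age_sex, C_pcs) {
  # A frozen threshold of zero means the observed run admitted nothing in
  # that layer; the permutation rerun then derives that layer's own
  # threshold (reporting cut-off for the scan, BH for the eQTL and
  # expression-metabolite layers), exactly as the original analysis would.
  mqtl_thr <- if (thresholds$mqtl_p > 0) thresholds$mqtl_p else cfg$p_report
  G <- hc$genotypes
  Yperm <- hc$metabolites$values[idxM, , drop = FALSE]
  rownames(Yperm) <- hc$metabolites$sample_ids
  Eperm <- hc$expression$values[idxE, , drop = FALSE]
  rownames(Eperm) <- hc$expression$sample_ids
  ## mQTL stage at the frozen validation threshold
  core <- scan_core(G$doses, Yperm, as_covariate_matrix(C_full))
  df <- rep(core$df, each = ncol(G$doses))
  p <- 2 * stats::pt(-abs(as.vector(core$t)), pmax(df, 1))
  sig <- which(!is.na(p) & p <= mqtl_thr)
  if (length(sig) == 0) return(0L)
  snp_i <- ((sig - 1L) %% ncol(G$doses)) + 1L
  met_j <- ((sig - 1L) %/% ncol(G$doses)) + 1L
  cand <- data.frame(x_id = colnames(G$doses)[snp_i],
    y_id = colnames(Yperm)[met_j],
    beta = as.vector(core$beta)[sig], p = p[sig],
    explained_var = as.vector(core$t)[sig]^2 / (as.vector(core$t)[sig]^2 + df[sig]),
    stringsAsFactors = FALSE)
  if (is.null(observed_leads)) {
    pr <- prune_lead_snps(cand, G, r2_max = cfg$prune_r2)
    pr <- assign_loci(pr, merge_bp = cfg$locus_merge_bp)
    mq <- pr$records
  } else {
    mq <- cand[cand$x_id %in% observed_leads$lead_snps$snp_id, , drop = FALSE]
    if (nrow(mq) == 0) return(0L)
    mq$locus_id <- observed_leads$lead_snps$locus_id[
      match(mq$x_id, observed_leads$lead_snps$snp_id)]
  }
  ## eQTL stage at the frozen layer thresholds
  lead_ids <- unique(mq$x_id)
  Epm <- hc$expression; Epm$values <- Eperm
  er <- assoc_scan(G$doses[, lead_ids, drop = FALSE], Eperm, C_pcs,
    layer = "eqtl")
  meta <- G$snps[match(er$x_id, G$snps$snp_id), ]
  pm <- hc$expression$probes[match(er$y_id, hc$expression$probes$probe_id), ]
  er$layer <- paste0("eqtl_", classify_cis_trans(meta$chrom, meta$pos,
    pm$chrom, pm$center, cfg$cis_window))
  cis <- er$layer == "eqtl_cis"
  thr_e <- if (thresholds$eqtl_cis > 0 || thresholds$eqtl_trans > 0) {
    list(cis = thresholds$eqtl_cis, trans = thresholds$eqtl_trans)
  } else {
    bh_layer_thresholds(er$p[cis], er$p[!cis], cfg$fdr)
  }
  er$significant <- ifelse(cis,
    !is.na(er$p) & er$p <= thr_e$cis & thr_e$cis > 0,
    !is.na(er$p) & er$p <= thr_e$trans & thr_e$trans > 0)
  if (!any(er$significant)) return(0L)
  ## expression-metabolite stage at the frozen threshold
  pairs <- candidate_pairs(er, mq)
  if (nrow(pairs) == 0) return(0L)
  Mpm <- hc$metabolites; Mpm$values <- Yperm
  ex <- exprmet_on_pairs(pairs, Epm, Mpm, C_age_sex, fdr = cfg$fdr,
    p_threshold = if (thresholds$exprmet_p > 0) thresholds$exprmet_p else NULL)
  tri <- build_triangles(mq, er, ex$records, mode = "strict")
  nrow(tri)
}

#' Write the pipeline's stage tables to a directory
#'
#' TSV exports mirroring the study's reporting layout: full scan, pruned
#' leads, proxies, replication, eQTL records, expression-metabolite
#' records, triangles, the causal report, and the network (GraphML +
#' JSON).
#'
#' @param res result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "NA")
  }
  wt(res$top, "mqtl_top.tsv")
  wt(res$leads$records, "mqtl_pruned_leads.tsv")
  wt(res$leads$lead_snps, "lead_snps.tsv")
  wt(res$proxies, "proxies.tsv")
  wt(res$replication, "replication.tsv")
  wt(res$eqtl$records, "eqtl.tsv")
  wt(res$exprmet$records, "expr_metab.tsv")
  wt(res$triangles, "triangles_strict.tsv")
  wt(res$triangles_exhaustive, "triangles_exhaustive.tsv")
  wt(res$causal, "causal_report.tsv")
  wt(data.frame(permutation = seq_along(res$triangle_null$counts),
    triangles = res$triangle_null$counts), "triangle_null_counts.tsv")
  write_network(res$network$nodes, res$network$edges,
    file.path(dir, "network.graphml"), format = "graphml")
  write_network(res$network$nodes, res$network$edges,
    file.path(dir, "network.json"), format = "json")
  invisible(dir)
}
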