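#!/usr/bin/env Rscript
# Stage 5 - eQTL mapping, expression-metabolite layer, triangles + null.
#
# Maps the validated lead SNPs against the prepared expression matrix
# (cis/trans split at 1 Mb inclusive, layer-specific BH thresholds at
# FDR 5%, confirmed by 100 permutations), tests the expression-
# metabolite candidate grid, closes association triangles, and sizes the
# chance expectation with 100 full-pipeline permutations and a Poisson
# tail test.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

prep <- get_prepared()
cfg <- prep$cfg
study <- prep$study

recs <- load_table("mqtl", "pruned_records.tsv")
lead_tab <- load_table("mqtl", "lead_snps.tsv")
leads <- structure(list(records = recs, lead_snps = lead_tab,
  r2_max = cfg$prune_r2), class = "lead_snp_set")
validated <- recs[!is.na(recs$q) & recs$q <= cfg$fdr, , drop = FALSE]
mqtl_thr <- if (nrow(validated) > 0) min(cfg$p_report, max(validated$p)) else 0

he <- harmonize_samples(genotypes = study$discovery$genotypes,
  expression = prep$E_d, covariates = study$discovery$covariates)
eqtl <- run_eqtl_scan(leads, he$genotypes, he$expression,
  subset_covariates(he$covariates, c("pc1", "pc2", "pc3")),
  fdr = cfg$fdr, cis_window = cfg$cis_window)
eq_sig <- eqtl$records[eqtl$records$significant, , drop = FALSE]
message(sprintf("eQTLs at FDR 5%%: %d cis (p <= %.3g), %d trans (p <= %.3g)",
  sum(eq_sig$layer == "eqtl_cis"), eqtl$thresholds$cis,
  sum(eq_sig$layer == "eqtl_trans"), eqtl$thresholds$trans))

lead_idx <- intersect(lead_tab$snp_id, colnames(he$genotypes$doses))
bh <- verify_bh_with_permutations(
  he$genotypes$doses[, lead_idx, drop = FALSE], he$expression$values,
  eqtl$records$layer == "eqtl_cis",
  subset_covariates(he$covariates, c("pc1", "pc2", "pc3")),
  alpha = cfg$fdr, n_perm = cfg$n_perm_bh_check, seed = cfg$seed + 303L)
message(sprintf("BH permutation check: empirical FDR cis %.3f, trans %.3f",
  bh$empirical_fdr_cis, bh$empirical_fdr_trans))

hc <- harmonize_samples(genotypes = study$discovery$genotypes,
  expression = prep$E_d, metabolites = prep$M_d,
  covariates = study$discovery$covariates)
pairs <- candidate_pairs(eqtl$records, validated)
exprmet <- exprmet_on_pairs(pairs, hc$expression, hc$metabolites,
  subset_covariates(hc$covariates, c("age", "sex")), fdr = cfg$fdr)
message("Expression-metabolite layer: ", nrow(pairs), " candidate pairs, ",
  sum(exprmet$records$significant), " significant")

tri <- build_triangles(validated, eqtl$records, exprmet$records, "strict")
tri_ex <- build_triangles(validated, eqtl$records, exprmet$records, "exhaustive")
message("Triangles: ", nrow(tri), " strict, ", nrow(tri_ex), " exhaustive")

thresholds <- list(mqtl_p = mqtl_thr, eqtl_cis = eqtl$thresholds$cis,
  eqtl_trans = eqtl$thresholds$trans, exprmet_p = exprmet$threshold)
tnull <- triangle_permutation_null(hc, cfg, thresholds,
  n_perm = cfg$n_perm_triangle, seed = cfg$seed + 404L)
pp <- poisson_tail_p(nrow(tri), tnull$lambda_hat)
message(sprintf(
  "Triangle null: mean %.3f over %d permutations; Poisson P(X >= %d) = %.3g",
  tnull$lambda_hat, tnull$n_perm, nrow(tri), pp))

save_table(eqtl$records, "integration", "eqtl.tsv")
save_table(data.frame(threshold_cis = eqtl$thresholds$cis,
  threshold_trans = eqtl$thresholds$trans,
  bh_empirical_fdr_cis = bh$empirical_fdr_cis,
  bh_empirical_fdr_trans = bh$empirical_fdr_trans,
  mqtl_p_threshold = mqtl_thr, exprmet_threshold = exprmet$threshold,
  triangle_null_mean = tnull$lambda_hat, poisson_tail_p = pp),
  "integration", "thresholds.tsv")
save_table(exprmet$records, "integration", "expr_metab.tsv")
save_table(tri, "integration", "triangles_strict.tsv")
save_table(tri_ex, "integration", "triangles_exhaustive.tsv")
save_table(data.frame(permutation = seq_along(tnull$counts),
  triangles = tnull$counts), "integration", "triangle_null_counts.tsv")
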