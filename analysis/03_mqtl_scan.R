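#!/usr/bin/env Rscript
# Stage 3 - discovery mQTL scan with permutation FDR, pruning, loci.
#
# Scans every (SNP, quantity) pair with covariate-adjusted OLS, checks
# genomic inflation, builds the 1000-permutation null (phenotype block
# permuted against genotypes+covariates) for empirical q-values, prunes
# the top list at LD r2 < 0.3 and merges lead SNPs into loci.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

prep <- get_prepared()
cfg <- prep$cfg
hm <- harmonize_samples(genotypes = prep$study$discovery$genotypes,
  metabolites = prep$M_d, covariates = prep$study$discovery$covariates)

message("Scanning ", ncol(hm$genotypes$doses), " SNPs x ",
  ncol(hm$metabolites$values), " quantities on n = ", hm$n, " ...")
scan <- run_mqtl_scan(hm$genotypes, hm$metabolites, hm$covariates,
  p_report = cfg$p_report)
message("  genomic lambda = ", round(scan$lambda, 4),
  "; pairs with p < 1e-7: ", nrow(scan$top))

message("Permutation null (", cfg$n_perm_mqtl, " permutations) ...")
obs <- scan_statistic(scan$scan$t, scan$scan$df, "neglog10p")
nul <- permute_phenotype_links(hm$genotypes, hm$metabolites, hm$covariates,
  n_perm = cfg$n_perm_mqtl, statistic_kind = "neglog10p",
  seed = cfg$seed + 101L)
scan$scan$q <- empirical_qvalues(obs, nul)
scan$top$q <- scan$scan$q[match(paste(scan$top$x_id, scan$top$y_id),
  paste(scan$scan$x_id, scan$scan$y_id))]

leads <- assign_loci(prune_lead_snps(scan$top, hm$genotypes,
  r2_max = cfg$prune_r2), merge_bp = cfg$locus_merge_bp)
message("  lead SNPs after pruning: ", nrow(leads$lead_snps),
  " at ", length(unique(leads$lead_snps$locus_id)), " loci")

save_table(scan$scan, "mqtl", "scan_full.tsv")
save_table(scan$top, "mqtl", "top.tsv")
save_table(leads$records, "mqtl", "pruned_records.tsv")
save_table(leads$lead_snps, "mqtl", "lead_snps.tsv")
save_table(data.frame(lambda = scan$lambda, n_tests = nrow(scan$scan),
  n_top = nrow(scan$top)), "mqtl", "scan_summary.tsv")
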