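#!/usr/bin/env Rscript
# Stage 4 - proxy search and direction-consistent replication.
#
# For each lead SNP, finds the best replication-panel proxy (r2 > 0.8 in
# the discovery cohort, within +/-50 kb, imputation info > 0.3), retests
# every discovery pair in the replication cohort (age+sex adjusted),
# orients effects by the lead-proxy dose correlation, and declares a pair
# replicated when its direction is consistent and its one-sided signed-z
# permutation q-value is <= 0.05.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

prep <- get_prepared()
cfg <- prep$cfg
G_d <- prep$study$discovery$genotypes
G_r <- prep$study$replication$genotypes

recs <- load_table("mqtl", "pruned_records.tsv")
lead_tab <- load_table("mqtl", "lead_snps.tsv")
leads <- structure(list(records = recs, lead_snps = lead_tab,
  r2_max = cfg$prune_r2), class = "lead_snp_set")

proxies <- find_proxies(leads, G_d, G_r, window_bp = cfg$proxy_window,
  r2_min = cfg$proxy_r2, info_min = cfg$info_min)
message("Proxies found for ", sum(!is.na(proxies$proxy_snp_id)), " of ",
  nrow(proxies), " lead SNPs (",
  sum(proxies$proxy_snp_id == proxies$lead_snp_id, na.rm = TRUE),
  " present in the replication panel themselves)")

hr <- harmonize_samples(genotypes = G_r, metabolites = prep$M_r,
  covariates = prep$study$replication$covariates)
repl <- replicate_associations(recs, proxies, G_d, hr$genotypes,
  hr$metabolites, subset_covariates(hr$covariates, c("age", "sex")),
  fdr = cfg$fdr, n_perm = cfg$n_perm_mqtl, seed = cfg$seed + 202L)

ok <- !is.na(repl$direction_consistent)
message(sprintf("Direction-consistent: %d/%d (%.1f%%); replicated at FDR 5%%: %d",
  sum(repl$direction_consistent[ok]), sum(ok),
  100 * mean(repl$direction_consistent[ok]),
  sum(repl$replicated, na.rm = TRUE)))

save_table(proxies, "replication", "proxies.tsv")
save_table(repl, "replication", "replication.tsv")
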