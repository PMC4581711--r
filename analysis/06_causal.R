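#!/usr/bin/env Rscript
# Stage 6 - adapted Mendelian randomization and mediation per triangle.
#
# For every strict triangle: the adapted-MR estimate of the expression
# effect on the metabolite (direct SNP path removed before forming the
# IV ratio) and the beta-attenuation mediation test, both with exact
# leave-one-out jackknife standard errors. Conclusions about causality
# rest on the mediation test, the more conservative of the two.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

prep <- get_prepared()
study <- prep$study
tri <- load_table("integration", "triangles_strict.tsv")
lead_tab <- load_table("mqtl", "lead_snps.tsv")

hc <- harmonize_samples(genotypes = study$discovery$genotypes,
  expression = prep$E_d, metabolites = prep$M_d,
  covariates = study$discovery$covariates)
causal <- summarize_causal(tri, hc$genotypes, hc$expression, hc$metabolites,
  hc$covariates, locus_map = lead_tab)

message("Causal summary over ", nrow(causal), " triangles:")
if (nrow(causal) > 0) {
  print(causal[, c("snp_id", "probe_id", "metabolite", "beta_mr", "p_mr",
    "delta", "p_mediation", "best_in_locus")], digits = 3)
  message(sum(causal$p_mediation < 0.05),
    " triangle(s) with nominally significant mediation")
}
save_table(causal, "causal", "causal_report.tsv")
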