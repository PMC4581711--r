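#!/usr/bin/env Rscript
# Stage 1 - simulate the two-cohort multi-omics study.
#
# Generates the discovery and replication cohorts (shared SNP panel and
# planted effects, independent individuals) and writes every input table
# in the pipeline's TSV dialect, plus the ground-truth effect table that
# later stages are scored against.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

message("Simulating study (seed ", STUDY_SEED, ") ...")
study <- get_study()

for (cohort in c("discovery", "replication")) {
  b <- study[[cohort]]
  d <- function(f) res_path("data", cohort, f)
  write_genotypes(b$genotypes, d("genotypes.tsv"), d("snp_annotation.tsv"))
  write_expression(b$expression, d("expression.tsv"), d("probe_annotation.tsv"),
    d("detection_p.tsv"))
  write_metabolites(b$metabolites, d("metabolites.tsv"),
    d("metabolite_defs.tsv"), d("below_lod.tsv"))
  write_covariates(b$covariates, d("covariates.tsv"))
  save_table(data.frame(sample_id = b$expression$sample_ids,
    batch = b$expression$batch), "data", cohort, "batches.tsv")
  message(sprintf("  %s: %d samples, %d SNPs, %d probes, %d metabolites",
    cohort, nrow(b$genotypes$doses), ncol(b$genotypes$doses),
    ncol(b$expression$values), ncol(b$metabolites$values)))
}
save_table(study$truth, "data", "truth.tsv")

message("Planted effects by kind:")
print(table(study$truth$kind))
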