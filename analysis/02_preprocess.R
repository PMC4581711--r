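#!/usr/bin/env Rscript
# Stage 2 - preprocess metabolites and expression.
#
# Metabolites: derive ratios/sums on the raw scale, dichotomize columns
# with >20% below-detection readings, arsinh-transform, and mask values
# outside mean +/- 5 SD. Expression: detection filter, quantile
# normalization + log2, the three sample-outlier rules, batch
# adjustment, and residualization on age/sex plus five expression PCs.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

prep <- get_prepared()

message("Metabolite panel after preparation:")
print(prep$M_d)
masked <- attr(prep$M_d, "n_masked")
message("  outliers masked: ", sum(masked), " values across ",
  sum(masked > 0), " columns")
save_table(data.frame(name = prep$M_d$defs$name, kind = prep$M_d$defs$kind,
  n_masked = as.integer(masked[prep$M_d$defs$name]),
  below_lod_frac = colMeans(prep$M_d$below_lod)), "prep", "metabolite_summary.tsv")

message("Expression matrix after preparation:")
print(prep$E_d)
qc <- attr(prep$E_d, "qc_report")
removed <- attr(prep$E_d, "removed_samples")
message("  probes retained: ", ncol(prep$E_d$values),
  "; samples removed by QC: ", nrow(removed))
save_table(qc, "prep", "expression_sample_qc.tsv")
save_table(removed, "prep", "expression_removed_samples.tsv")
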