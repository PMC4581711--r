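#!/usr/bin/env Rscript
# Stage 7 - assemble and export the significant-association network.
#
# Nodes are loci (flagged when they carry triangles), cis/trans genes and
# metabolite traits; edges are the significant associations of the three
# layers, weighted by explained variance. Written as GraphML and JSON
# node-link for downstream viewers.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

prep <- get_prepared()
cfg <- prep$cfg

recs <- load_table("mqtl", "pruned_records.tsv")
validated <- recs[!is.na(recs$q) & recs$q <= cfg$fdr, , drop = FALSE]
eqtl <- load_table("integration", "eqtl.tsv")
exprmet <- load_table("integration", "expr_metab.tsv")
tri_ex <- load_table("integration", "triangles_exhaustive.tsv")
lead_tab <- load_table("mqtl", "lead_snps.tsv")

net <- build_network(validated, eqtl, exprmet, prep$M_d, prep$E_d,
  triangles = tri_ex, lead_loci = lead_tab)
message("Network: ", nrow(net$nodes), " nodes, ", nrow(net$edges), " edges")
print(table(net$nodes$role))

write_network(net$nodes, net$edges, res_path("network", "network.graphml"),
  "graphml")
write_network(net$nodes, net$edges, res_path("network", "network.json"),
  "json")
save_table(net$nodes, "network", "nodes.tsv")
save_table(net$edges, "network", "edges.tsv")
message("Network written under results/network/")
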