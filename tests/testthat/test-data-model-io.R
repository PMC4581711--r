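test_that("genotype TSV round-trips exactly and validates bounds", {
  d <- withr::local_tempdir()
  doses <- matrix(c(0, 1, 2, 0.5, 1.5, 0.73), 3, 2,
    dimnames = list(c("A", "B", "C"), c("rs1", "rs2")))
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
    allele_ref = "A", allele_alt = "G", maf = c(0.2, 0.3), info = c(0.9, 1))
  G <- genotype_matrix(doses, snps)
  write_genotypes(G, file.path(d, "g.tsv"), file.path(d, "a.tsv"))
  G2 <- read_genotypes(file.path(d, "g.tsv"), "tsv", file.path(d, "a.tsv"))
  expect_equal(G2$doses, G$doses, tolerance = 1e-12)
  expect_identical(G2$snps$snp_id, G$snps$snp_id)
  bad <- doses; bad[2, 1] <- 2.5
  expect_error(genotype_matrix(bad, snps), "outside \\[0,2\\].*rs1")
  expect_error(genotype_matrix(doses, transform(snps, snp_id = c("rs1", "rs1"))),
    "duplicate")
})

test_that("a hand-written one-record VCF parses DS dosages", {
  d <- withr::local_tempdir()
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t12345\trs1\tA\tG\t.\tPASS\t.\tGT:DS\t0/1:0.73\t1/1:1.92"),
    file.path(d, "t.vcf"))
  G <- read_genotypes(file.path(d, "t.vcf"), "vcf")
  expect_equal(unname(G$doses["S1", "rs1"]), 0.73)
  expect_equal(unname(G$doses["S2", "rs1"]), 1.92)
  expect_identical(G$snps$chrom, "1")
})

test_that("sample harmonization intersects, warns, and is order-independent", {
  doses <- matrix(runif(8, 0, 2), 4, 2,
    dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  snps <- data.frame(snp_id = c("s1", "s2"), chrom = "1", pos = c(1L, 2L),
    allele_ref = "A", allele_alt = "G", maf = 0.3, info = 1)
  G <- genotype_matrix(doses, snps)
  cv <- covariate_table(data.frame(age = c(50, 60, 70),
    row.names = c("B", "C", "E")))
  expect_message(h <- harmonize_samples(genotypes = G, covariates = cv),
    "intersection")
  expect_identical(h$genotypes$sample_ids, c("B", "C"))
  expect_identical(h$n, 2L)
  # permuting input row order does not change harmonized content
  G2 <- genotype_matrix(doses[c(3, 1, 4, 2), ], snps)
  h2 <- suppressMessages(harmonize_samples(genotypes = G2, covariates = cv))
  expect_equal(h2$genotypes$doses[h$genotypes$sample_ids, ],
    h$genotypes$doses, tolerance = 1e-12)
  cv2 <- covariate_table(data.frame(age = 1:3, row.names = c("X", "Y", "Z")))
  expect_error(harmonize_samples(genotypes = G, covariates = cv2), "empty")
})

test_that("metabolite definitions enforce referential integrity on read", {
  d <- withr::local_tempdir()
  vals <- data.frame(sample_id = c("A", "B"), M1 = c(1, 2), M2 = c(3, 4))
  write.table(vals, file.path(d, "m.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  defs <- data.frame(name = c("M1", "M2", "R1"), kind = c("raw", "raw", "ratio"),
    numerator = c("", "", "M1"), denominator = c("", "", "M9"), lod = NA)
  write.table(defs, file.path(d, "d.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metabolites(file.path(d, "m.tsv"), file.path(d, "d.tsv")),
    "unknown raw name")
  defs$denominator[3] <- "M2"
  write.table(defs, file.path(d, "d.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  p <- read_metabolites(file.path(d, "m.tsv"), file.path(d, "d.tsv"))
  expect_identical(attr(p, "pending_defs")$name, "R1")
})

test_that("network files round-trip with exact weights and reject dangling edges", {
  d <- withr::local_tempdir()
  nodes <- data.frame(id = c("snp", "gene", "met"),
    role = c("locus", "cis_gene", "raw_metabolite"))
  edges <- data.frame(from = c("snp", "snp", "gene"), to = c("gene", "met", "met"),
    layer = c("eqtl_cis", "mqtl", "expr_metab"),
    explained_var = c(0.137, 0.042, 0.09))
  for (fmt in c("graphml", "json")) {
    f <- file.path(d, paste0("n.", fmt))
    write_network(nodes, edges, f, fmt)
    back <- read_network(f, fmt)
    expect_equal(sort(as.numeric(back$edges$explained_var)),
      sort(edges$explained_var), tolerance = 1e-12)
    expect_setequal(back$nodes$id, nodes$id)
  }
  bad <- rbind(edges, data.frame(from = "ghost", to = "met",
    layer = "mqtl", explained_var = 0.1))
  expect_error(write_network(nodes, bad, file.path(d, "x.graphml")), "dangling")
  # empty graph is fine
  write_network(nodes[0, ], edges[0, ], file.path(d, "e.json"), "json")
  eg <- read_network(file.path(d, "e.json"), "json")
  expect_equal(nrow(eg$edges), 0)
})

test_that("run configuration defaults to the study constants and rejects bad keys", {
  d <- withr::local_tempdir()
  writeLines("", file.path(d, "empty.yaml"))
  cfg <- validate_config(file.path(d, "empty.yaml"))
  expect_equal(cfg$p_report, 1e-7)
  expect_equal(cfg$fdr, 0.05)
  expect_equal(cfg$prune_r2, 0.3)
  expect_equal(cfg$proxy_r2, 0.8)
  expect_equal(cfg$proxy_window, 50000L)
  expect_equal(cfg$cis_window, 1000000L)
  expect_equal(cfg$n_perm_mqtl, 1000L)
  expect_equal(cfg$n_perm_triangle, 100L)
  expect_equal(cfg$outlier_k, 5)
  expect_equal(cfg$lod_frac, 0.20)
  writeLines("fdr: 1.5", file.path(d, "bad.yaml"))
  expect_error(validate_config(file.path(d, "bad.yaml")), "fdr")
  writeLines("frd: 0.05", file.path(d, "unk.yaml"))
  expect_error(validate_config(file.path(d, "unk.yaml")), "valid keys")
})
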