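test_that("cis/trans classification is inclusive at exactly 1 Mb", {
  expect_identical(classify_cis_trans("1", 5000000, "1", 6000000), "cis")
  expect_identical(classify_cis_trans("1", 5000000, "1", 6000001), "trans")
  expect_identical(classify_cis_trans("1", 5000000, "2", 5000000), "trans")
  expect_identical(classify_cis_trans("1", 1, "1", 1000001.5), "trans")
  expect_error(classify_cis_trans("1", NA, "1", 5), "missing coordinates")
})

sig_rec <- function(x, y, layer, p = 1e-10, beta = 0.5) {
  data.frame(x_id = x, y_id = y, layer = layer, beta = beta, se = 0.05,
    t = 10, p = p, n = 100, df = 98, explained_var = 0.1,
    significant = TRUE, stringsAsFactors = FALSE)
}

test_that("triangle closure counts follow the combinatorics", {
  mq <- sig_rec("snp", "met", "mqtl"); mq$locus_id <- "L01"
  eq <- sig_rec("snp", "probe", "eqtl_cis")
  em <- sig_rec("probe", "met", "expr_metab")
  tr <- build_triangles(mq, eq, em, mode = "strict")
  expect_equal(nrow(tr), 1L)
  expect_identical(tr$cis_or_trans, "cis")
  # missing probe-metabolite edge -> no triangle
  em0 <- em; em0$significant <- FALSE
  expect_equal(nrow(build_triangles(mq, eq, em0, mode = "strict")), 0L)
  # 2 probes x 2 metabolites, all closures significant -> 4 in exhaustive mode
  mq2 <- rbind(sig_rec("snp", "metA", "mqtl"), sig_rec("snp", "metB", "mqtl"))
  mq2$locus_id <- "L01"
  eq2 <- rbind(sig_rec("snp", "p1", "eqtl_cis"), sig_rec("snp", "p2", "eqtl_cis"))
  em2 <- rbind(sig_rec("p1", "metA", "expr_metab"), sig_rec("p1", "metB", "expr_metab"),
    sig_rec("p2", "metA", "expr_metab"), sig_rec("p2", "metB", "expr_metab"))
  expect_equal(nrow(build_triangles(mq2, eq2, em2, mode = "exhaustive")), 4L)
  # strict mode keeps only the top SNP's best metabolite
  mq3 <- mq2; mq3$p <- c(1e-12, 1e-8)
  tr3 <- build_triangles(mq3, eq2, em2, mode = "strict")
  expect_equal(nrow(tr3), 2L)            # one per probe
  expect_setequal(unique(tr3$metabolite), "metA")
})

test_that("triangle edges store the edge statistics verbatim", {
  mq <- sig_rec("snp", "met", "mqtl", p = 2e-9, beta = 0.31); mq$locus_id <- "L01"
  eq <- sig_rec("snp", "probe", "eqtl_trans", p = 3e-15, beta = -0.52)
  em <- sig_rec("probe", "met", "expr_metab", p = 1e-4, beta = 0.2)
  tr <- build_triangles(mq, eq, em, mode = "strict")
  expect_equal(tr$beta_mqtl, 0.31)
  expect_equal(tr$beta_eqtl, -0.52)
  expect_equal(tr$p_exprmet, 1e-4)
  expect_identical(tr$cis_or_trans, "trans")
})

test_that("poisson tail probability matches closed forms and is monotone", {
  expect_equal(poisson_tail_p(0, 5), 1.0)
  expect_equal(poisson_tail_p(2, 1), 1 - 2 * exp(-1), tolerance = 1e-7)
  expect_equal(poisson_tail_p(2, 1), 0.2642411, tolerance = 1e-7)
  expect_equal(poisson_tail_p(3, 0), 0.0)
  ks <- 0:10
  ps <- vapply(ks, poisson_tail_p, 1, lambda_hat = 2)
  expect_true(all(diff(ps) <= 0))
  lams <- seq(0, 5, by = 0.5)
  pl <- vapply(lams, function(l) poisson_tail_p(3, l), 1)
  expect_true(all(diff(pl) >= 0))
})

test_that("the eQTL scan labels layers and applies layer-specific thresholds", {
  set.seed(51)
  n <- 1000
  doses <- cbind(s1 = rbinom(n, 2, 0.3), s2 = rbinom(n, 2, 0.4))
  snps <- data.frame(snp_id = c("s1", "s2"), chrom = c("1", "2"),
    pos = c(5000000L, 8000000L), allele_ref = "A", allele_alt = "G",
    maf = 0.3, info = 1)
  G <- genotype_matrix(doses, snps)
  ev <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("P%02d", 1:20)))
  ev[, 1] <- ev[, 1] + 0.45 * doses[, "s1"]    # cis to s1 (placed nearby)
  probes <- data.frame(probe_id = colnames(ev), gene_symbol = colnames(ev),
    chrom = c("1", rep("7", 19)),
    start = c(5400000L, seq(1e6, by = 2e6, length.out = 19)),
    end = c(5400100L, seq(1e6, by = 2e6, length.out = 19) + 100))
  E <- expression_matrix(ev, probes)
  res <- run_eqtl_scan(c("s1", "s2"), G, E)
  r11 <- res$records[res$records$x_id == "s1" & res$records$y_id == "P01", ]
  expect_identical(r11$layer, "eqtl_cis")
  expect_true(r11$significant)
  expect_true(all(res$records$layer[res$records$y_id != "P01"] == "eqtl_trans"))
  expect_equal(res$records$explained_var,
    res$records$t^2 / (res$records$t^2 + res$records$df), tolerance = 1e-12)
})

test_that("network assembly types nodes and keeps one edge per association", {
  mq <- sig_rec("snp", "met", "mqtl"); mq$locus_id <- "L01"
  eq <- rbind(sig_rec("snp", "p1", "eqtl_cis"), sig_rec("snp", "p2", "eqtl_trans"))
  em <- sig_rec("p1", "met", "expr_metab")
  panel <- random_panel(matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("met", "o"))),
    kinds = c("ratio", "raw"))
  E <- NULL
  tri <- build_triangles(mq, eq, em, mode = "exhaustive")
  net <- build_network(mq, eq, em, panel, E, triangles = tri)
  expect_equal(nrow(net$edges), nrow(mq) + nrow(eq) + nrow(em))
  expect_true(all(net$edges$explained_var >= 0 & net$edges$explained_var < 1))
  roles <- setNames(net$nodes$role, net$nodes$id)
  expect_identical(unname(roles["snp"]), "locus_with_triangles")
  expect_identical(unname(roles["p1"]), "cis_gene")
  expect_identical(unname(roles["p2"]), "trans_gene")
  expect_identical(unname(roles["met"]), "metabolite_ratio")
})
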