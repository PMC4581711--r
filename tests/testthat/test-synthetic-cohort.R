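test_that("genotype simulation is deterministic and respects LD structure", {
  cfg <- sim_config(seed = 3, n_snps = 40, ld_block_size = 4)
  g1 <- simulate_genotypes(500, cfg, seed = 9)
  g2 <- simulate_genotypes(500, cfg, seed = 9)
  expect_identical(g1$doses, g2$doses)
  g3 <- simulate_genotypes(500, cfg, seed = 10)
  expect_false(identical(g1$doses, g3$doses))
  expect_true(all(g1$doses >= 0 & g1$doses <= 2))
  # built-in proxy: SNP 2 copies SNP 1's haplotype column
  expect_gt(ld_r2(g1, "b01s1", "b01s2"), 0.9)
  # across blocks r2 ~ 0
  cfg1 <- sim_config(seed = 3, n_snps = 30, ld_block_size = 1)
  gind <- simulate_genotypes(2000, cfg1, seed = 11)
  offdiag <- cor(gind$doses)^2; diag(offdiag) <- NA
  expect_lt(max(offdiag, na.rm = TRUE), 0.05)
  expect_error(simulate_genotypes(1, cfg), "at least 2")
})

test_that("empirical MAF tracks the recorded MAF within the binomial bound", {
  cfg <- sim_config(seed = 5, n_snps = 30, ld_block_size = 1,
    maf_range = c(0.3, 0.3))
  n <- 2000
  g <- simulate_genotypes(n, cfg, seed = 12)
  emp <- pmin(colMeans(g$doses) / 2, 1 - colMeans(g$doses) / 2)
  bound <- 3 * sqrt(0.3 * 0.7 / (2 * n))
  # recorded maf comes from the drawn haplotypes; compare to the pool target
  expect_true(all(abs(emp - g$snps$maf) < 0.05))
  expect_true(mean(abs(emp - 0.3) < 0.3 * 0.5) > 0.9)  # pool discretization
  expect_true(all(abs(emp - round(emp * 20 * 2) / 40) < bound + 0.05))
  expect_true(all(g$snps$info > 0.5 & g$snps$info <= 1))
})

test_that("expression simulation plants recoverable cis effects and batch structure", {
  cfg <- sim_config(seed = 6, n_discovery = 2000)
  truth <- default_truth(cfg)
  G <- simulate_genotypes(2000, cfg, seed = 13)
  E <- simulate_expression(G, truth, cfg, seed = 14)
  lat <- attr(E, "latent_bio")
  f <- fit_ols(lat[, "P001"], G$doses[, "b07s1"])
  expect_lt(abs(f$beta - 0.8), 3 * f$se)
  # cis probes placed within 1 Mb, trans on another chromosome
  snp7 <- G$snps[G$snps$snp_id == "b07s1", ]
  pr1 <- E$probes[E$probes$probe_id == "P001", ]
  expect_identical(pr1$chrom, snp7$chrom)
  expect_lte(abs(pr1$center - snp7$pos), 1e6)
  snp12 <- G$snps[G$snps$snp_id == "b12s1", ]
  pr6 <- E$probes[E$probes$probe_id == "P006", ]
  expect_false(pr6$chrom == snp12$chrom)
  # no planted effect -> no SNP correlation beyond noise
  r0 <- abs(cor(lat[, "P050"], G$doses[, "b01s1"]))
  expect_lt(r0, 3 / sqrt(2000))
})

test_that("metabolite simulation yields mediated conditional independence and LOD flags", {
  cfg <- sim_config(seed = 7, n_discovery = 2000)
  truth <- default_truth(cfg)
  G <- simulate_genotypes(2000, cfg, seed = 15)
  C <- simulate_covariates(G$sample_ids, seed = 16)
  E <- simulate_expression(G, truth, cfg, seed = 17)
  M <- simulate_metabolites(G, E, C, truth, cfg, seed = 18)
  # mediated-only: SNP -> P001 -> M07; partial correlation given expression ~ 0
  lat <- attr(E, "latent_bio")
  y <- log(M$values[, "M07"])   # latent recovered up to LOD-censoring
  ok <- is.finite(y)
  ry <- resid(lm(y[ok] ~ lat[ok, "P001"]))
  rg <- resid(lm(G$doses[ok, "b07s1"] ~ lat[ok, "P001"]))
  expect_lt(abs(cor(ry, rg)), 3 / sqrt(sum(ok)))
  # below-LOD fractions near their configured quantiles
  bl <- colMeans(M$below_lod)
  expect_equal(unname(bl["M01"]), 0.05, tolerance = 0.01)
  expect_equal(unname(bl["M20"]), 0.30, tolerance = 0.02)
})

test_that("a global-null simulation yields uniform scan p-values", {
  cfg <- sim_config(seed = 8, n_discovery = 500, n_snps = 500,
    ld_block_size = 1, n_metabolites = 10, lod_quantile = 0, n_high_lod = 0)
  null_truth <- default_truth(cfg)[0, ]
  G <- simulate_genotypes(500, cfg, seed = 19)
  C <- simulate_covariates(G$sample_ids, seed = 20)
  E <- simulate_expression(G, null_truth, cfg, seed = 21)
  M <- simulate_metabolites(G, E, C, null_truth, cfg, seed = 22)
  sc <- run_mqtl_scan(G, M, C)
  ks <- suppressWarnings(ks.test(sc$scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(sc$lambda, 0.9); expect_lt(sc$lambda, 1.1)
})

test_that("the two-cohort study shares effects, is deterministic, and drops SNPs for proxy search", {
  s1 <- simulate_study(sim_config(seed = 42, n_discovery = 400, n_replication = 200))
  s2 <- simulate_study(sim_config(seed = 42, n_discovery = 400, n_replication = 200))
  expect_identical(s1$discovery$genotypes$doses, s2$discovery$genotypes$doses)
  expect_identical(s1$replication$metabolites$values, s2$replication$metabolites$values)
  expect_lt(ncol(s1$replication$genotypes$doses), ncol(s1$discovery$genotypes$doses))
  # replication recovery of a planted direct effect (0.5 on M01 at b01s1)
  big <- simulate_study(sim_config(seed = 5, n_replication = 1000))
  Mr <- prepare_metabolites(big$replication$metabolites)
  f <- fit_ols(Mr$values[, "M01"], big$replication$genotypes$doses[, "b01s1"],
    big$replication$covariates$data[, c("age", "sex")])
  expect_lt(abs(f$beta - 0.5), 3 * f$se + 0.1)  # arsinh scale compresses slightly
  expect_gt(f$t, 5)
})

test_that("planted variance fractions match the heritability identity", {
  study <- simulate_study(sim_config(seed = 31))
  G <- study$discovery$genotypes
  M <- study$discovery$metabolites
  y <- log(M$values[, "M01"])
  ok <- is.finite(y)
  g <- G$doses[ok, "b01s1"]
  planted_frac <- 0.5^2 * var(g) / var(y[ok])
  f <- fit_ols(y, G$doses[, "b01s1"])
  expect_lt(abs(f$explained_var - planted_frac) / planted_frac, 0.30)
})
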