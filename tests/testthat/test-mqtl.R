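make_geno <- function(doses, chrom = "1", pos = NULL) {
  m <- ncol(doses)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  snps <- data.frame(snp_id = colnames(doses), chrom = rep(chrom, length.out = m),
    pos = pos, allele_ref = "A", allele_alt = "G",
    maf = pmin(colMeans(doses) / 2, 1 - colMeans(doses) / 2), info = 1)
  genotype_matrix(doses, snps)
}

test_that("ld_r2 covers identity, independence, and noisy duplicates", {
  set.seed(41)
  n <- 2000
  a <- rbinom(n, 2, 0.3); b <- rbinom(n, 2, 0.4)
  dup <- pmin(pmax(a + rnorm(n, 0, 0.05), 0), 2)
  G <- make_geno(cbind(a = a, b = b, dup = dup))
  expect_equal(ld_r2(G, "a", "a"), 1.0)
  expect_lt(ld_r2(G, "a", "b"), 0.01)
  expect_gt(ld_r2(G, "a", "dup"), 0.98)
  Gm <- make_geno(cbind(a = a, mono = rep(1, n)))
  expect_error(ld_r2(Gm, "a", "mono"), "monomorphic")
})

test_that("greedy pruning matches the brute-force oracle on a 5-SNP instance", {
  set.seed(43)
  n <- 800
  base1 <- rbinom(n, 2, 0.3); base2 <- rbinom(n, 2, 0.4)
  doses <- cbind(
    s1 = base1,
    s2 = pmin(pmax(base1 + rnorm(n, 0, 0.3), 0), 2),   # correlated with s1
    s3 = base2,
    s4 = pmin(pmax(base2 + rnorm(n, 0, 0.25), 0), 2),  # correlated with s3
    s5 = rbinom(n, 2, 0.2))                            # independent
  G <- make_geno(doses)
  minp <- c(s1 = 1e-9, s2 = 1e-8, s3 = 1e-12, s4 = 1e-10, s5 = 1e-7)
  top <- data.frame(x_id = names(minp), y_id = "m", layer = "mqtl",
    beta = 1, se = 0.1, t = 10, p = unname(minp), n = n, df = n - 2,
    explained_var = 0.1)
  pruned <- prune_lead_snps(top, G, r2_max = 0.3)
  r2mat <- cor(doses)^2
  expect_identical(sort(pruned$lead_snps$snp_id),
    sort(colnames(doses)[prune_oracle(minp, r2mat)]))
  # retained set has max pairwise r2 < 0.3
  kept <- pruned$lead_snps$snp_id
  if (length(kept) > 1) {
    pairs <- combn(kept, 2)
    r2s <- apply(pairs, 2, function(pr) ld_r2(G, pr[1], pr[2]))
    expect_lt(max(r2s), 0.3)
  }
  # every discarded SNP has r2 >= 0.3 with a retained SNP of smaller or equal p
  dropped <- setdiff(names(minp), kept)
  for (s in dropped) {
    partners <- kept[minp[kept] <= minp[s]]
    expect_true(any(vapply(partners, function(k) ld_r2(G, s, k), 1) >= 0.3))
  }
  # two perfect duplicates: the smaller p wins
  G2 <- make_geno(cbind(a = base1, b = base1 + 0))
  top2 <- top[1:2, ]; top2$x_id <- c("a", "b"); top2$p <- c(1e-9, 1e-8)
  expect_identical(prune_lead_snps(top2, G2)$lead_snps$snp_id, "a")
})

test_that("locus assignment merges by single linkage at 1 Mb", {
  mk_leads <- function(chrom, pos) {
    ids <- paste0("s", seq_along(pos))
    structure(list(
      records = data.frame(x_id = ids, y_id = "m", p = 1e-9,
        beta = 1, se = 0.1, explained_var = 0.1),
      lead_snps = data.frame(snp_id = ids, min_p = 1e-9, chrom = chrom,
        pos = pos, rank = seq_along(pos)),
      r2_max = 0.3), class = "lead_snp_set")
  }
  a <- assign_loci(mk_leads("1", c(1000000, 1500000)))
  expect_equal(length(unique(a$lead_snps$locus_id)), 1L)
  b <- assign_loci(mk_leads(c("1", "2"), c(1000000, 1000000)))
  expect_equal(length(unique(b$lead_snps$locus_id)), 2L)
  # chain A-B 0.9 Mb, B-C 0.9 Mb, A-C 1.8 Mb -> one locus by single linkage
  ch <- assign_loci(mk_leads("3", c(1000000, 1900000, 2800000)))
  expect_equal(length(unique(ch$lead_snps$locus_id)), 1L)
})

test_that("proxy search honours window, LD and info rules", {
  set.seed(44)
  n <- 1500
  lead <- rbinom(n, 2, 0.3)
  good <- pmin(pmax(lead + rnorm(n, 0, 0.05), 0), 2)   # r2 ~ 1
  weak <- ifelse(runif(n) < 0.5, lead, rbinom(n, 2, 0.3))  # r2 ~ 0.5
  far <- pmin(pmax(lead + rnorm(n, 0, 0.05), 0), 2)
  G_disc <- make_geno(cbind(lead = lead, good = good, weak = weak, far = far),
    pos = c(100000L, 110000L, 120000L, 200000L))     # far is 100 kb away
  leads <- structure(list(lead_snps = data.frame(snp_id = "lead", min_p = 1e-9,
    chrom = "1", pos = 100000L, rank = 1L)), class = "lead_snp_set")
  # replication panel lacking the lead: good proxy within 50 kb wins
  G_rep <- subset_geno <- make_geno(cbind(good = good, weak = weak, far = far),
    pos = c(110000L, 120000L, 200000L))
  pr <- find_proxies(leads, G_disc, G_rep)
  expect_identical(pr$proxy_snp_id, "good")
  expect_gt(pr$r2, 0.8)
  # lead present in replication: proxy = itself
  pr2 <- find_proxies(leads, G_disc, G_disc)
  expect_identical(pr2$proxy_snp_id, "lead")
  expect_equal(pr2$r2, 1)
  # only the far (outside-window) and weak (low-LD) candidates: unreplicable
  G_rep3 <- make_geno(cbind(weak = weak, far = far), pos = c(120000L, 200000L))
  G_rep3$snps$pos[2] <- 160000L   # 60 kb away: outside the +/-50 kb window
  pr3 <- find_proxies(leads, G_disc, G_rep3)
  expect_true(is.na(pr3$proxy_snp_id))
  # low info disqualifies
  G_rep4 <- make_geno(cbind(good = good), pos = 110000L)
  G_rep4$snps$info <- 0.2
  pr4 <- find_proxies(leads, G_disc, G_rep4)
  expect_true(is.na(pr4$proxy_snp_id))
})

test_that("replication orients negatively correlated proxies correctly", {
  set.seed(45)
  n <- 1200
  lead <- rbinom(n, 2, 0.4)
  flipped <- pmin(pmax(2 - lead + rnorm(n, 0, 0.05), 0), 2)  # r ~ -1
  y <- 0.4 * lead + rnorm(n)
  G_disc <- make_geno(cbind(lead = lead, flip = flipped), pos = c(1e5L, 11e4L))
  panel <- random_panel(matrix(y, ncol = 1, dimnames = list(NULL, "m")))
  panel$stage <- "masked"
  top <- data.frame(x_id = "lead", y_id = "m", layer = "mqtl",
    beta = 0.4, se = 0.03, t = 13, p = 1e-30, n = n, df = n - 2,
    explained_var = 0.1, q = 0)
  proxies <- data.frame(lead_snp_id = "lead", proxy_snp_id = "flip",
    r2 = 0.98, distance = 10000L, proxy_info = 1)
  rep <- replicate_associations(top, proxies, G_disc, G_disc, panel,
    n_perm = 30, seed = 4)
  expect_equal(rep$orientation, -1)
  expect_true(rep$direction_consistent)
  expect_lt(abs(rep$beta_rep - 0.4), 3 * rep$se_rep)
  expect_true(rep$replicated)
})

test_that("mQTL scan finds planted effects and is invariant to row order", {
  set.seed(46)
  n <- 2000
  doses <- cbind(hit = rbinom(n, 2, 0.3), nul = rbinom(n, 2, 0.3))
  G <- make_geno(doses)
  y <- 0.5 * doses[, "hit"] + rnorm(n)
  panel <- matrix(cbind(y, rnorm(n)), n, 2, dimnames = list(NULL, c("m1", "m2")))
  sc <- run_mqtl_scan(G, panel, p_report = 1e-7)
  expect_true(any(sc$top$x_id == "hit" & sc$top$y_id == "m1"))
  expect_false(any(sc$top$x_id == "nul"))
  perm <- sample(n)
  G2 <- make_geno(doses[perm, ])
  sc2 <- run_mqtl_scan(G2, panel[perm, , drop = FALSE], p_report = 1e-7)
  expect_equal(sc2$scan$p, sc$scan$p, tolerance = 1e-10)
})
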