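sim_chain <- function(n, a = 0.5, b = 0.4, direct = 0, maf = 0.3, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 2, maf)
  e <- a * g + rnorm(n)
  y <- b * e + direct * g + rnorm(n)
  list(g = g, e = e, y = y)
}

test_that("adapted MR recovers the expression effect with and without a direct path", {
  d <- sim_chain(2000, a = 0.5, b = 0.4, direct = 0, seed = 61)
  mr <- mr_adapted(d$g, d$e, d$y)
  expect_lt(abs(mr$beta_mr - 0.4), 3 * mr$se_jack)
  expect_false(mr$weak_instrument)
  # the defining property: a direct SNP path of 0.3 does not bias the estimate
  d2 <- sim_chain(2000, a = 0.5, b = 0.4, direct = 0.3, seed = 62)
  mr2 <- mr_adapted(d2$g, d2$e, d2$y)
  expect_lt(abs(mr2$beta_mr - 0.4), 3 * mr2$se_jack)
  expect_lt(abs(mr2$direct_beta_removed - 0.3), 0.15)
  # null outcome
  set.seed(63)
  g <- rbinom(2000, 2, 0.3); e <- 0.5 * g + rnorm(2000); y <- rnorm(2000)
  mr3 <- mr_adapted(g, e, y)
  expect_lt(abs(mr3$beta_mr), 3 * mr3$se_jack)
})

test_that("MR consistency: small relative bias averaged over seeds", {
  est <- vapply(1:20, function(s) {
    d <- sim_chain(2000, a = 0.5, b = 0.4, direct = 0, seed = 100 + s)
    mr_adapted(d$g, d$e, d$y)$beta_mr
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4) / 0.4, 0.05)
})

test_that("MR flags weak instruments and agrees in sign with the exposure-outcome link", {
  set.seed(65)
  g <- rbinom(500, 2, 0.3); e <- rnorm(500); y <- 0.4 * e + rnorm(500)
  mr <- mr_adapted(g, e, y)
  expect_true(mr$weak_instrument)
  expect_true(is.na(mr$p))
  # orientation coherence under a positive instrument-exposure effect
  d <- sim_chain(2000, a = 0.6, b = -0.3, seed = 65)
  mr2 <- mr_adapted(d$g, d$e, d$y)
  f <- fit_ols(d$y, d$e)
  expect_identical(sign(mr2$beta_mr), sign(f$beta))
})

test_that("fast jackknife equals brute-force leave-one-out refitting", {
  d <- sim_chain(60, a = 0.5, b = 0.4, direct = 0.2, seed = 66)
  C <- cbind(age = rnorm(60))
  mr <- mr_adapted(d$g, d$e, d$y, C)
  brute <- vapply(1:60, function(i) {
    g <- d$g[-i]; e <- d$e[-i]; y <- d$y[-i]; Ci <- C[-i, , drop = FALSE]
    cdir <- coef(lm(y ~ g + e + Ci))["g"]
    (coef(lm(y ~ g + Ci))["g"] - cdir) / coef(lm(e ~ g + Ci))["g"]
  }, numeric(1))
  se_brute <- sqrt(59 / 60 * sum((brute - mean(brute))^2))
  expect_equal(mr$se_jack, se_brute, tolerance = 1e-10)
  med <- mediation_attenuation_test(d$g, d$e, d$y, C)
  brute_d <- vapply(1:60, function(i) {
    g <- d$g[-i]; e <- d$e[-i]; y <- d$y[-i]; Ci <- C[-i, , drop = FALSE]
    abs(coef(lm(y ~ g + Ci))["g"]) - abs(coef(lm(y ~ g + e + Ci))["g"])
  }, numeric(1))
  se_bd <- sqrt(59 / 60 * sum((brute_d - mean(brute_d))^2))
  expect_equal(med$se_jack_delta, se_bd, tolerance = 1e-10)
})

test_that("mediation test attenuates under mediation and stays null otherwise", {
  # full mediation: delta ~ |beta_without|
  d <- sim_chain(2000, a = 0.56, b = 0.4, direct = 0, seed = 67)
  med <- mediation_attenuation_test(d$g, d$e, d$y)
  expect_lt(abs(med$delta - abs(med$beta_without)) / abs(med$beta_without), 0.4)
  expect_lt(med$p_delta, 0.05)
  # e independent of g and y: delta ~ 0
  set.seed(68)
  g <- rbinom(2000, 2, 0.3); e <- rnorm(2000); y <- 0.3 * g + rnorm(2000)
  med0 <- mediation_attenuation_test(g, e, y)
  expect_lt(abs(med0$delta), 3 * med0$se_jack_delta)
  # partial mediation: about half the effect routes through e
  set.seed(69)
  g <- rbinom(2000, 2, 0.3)
  e <- 0.5 * g + rnorm(2000)
  y <- 0.4 * e + 0.2 * g + rnorm(2000)   # mediated path 0.2/dose, direct 0.2/dose
  medp <- mediation_attenuation_test(g, e, y)
  expect_gt(medp$delta / abs(medp$beta_without), 0.3)
  expect_lt(medp$delta / abs(medp$beta_without), 0.7)
})

test_that("causal summary reports per-triangle statistics and flags the best triple", {
  study <- tiny_study()
  res <- tiny_pipeline()
  if (nrow(res$triangles) > 0) {
    expect_true(all(c("beta_mr", "p_mr", "delta", "p_mediation") %in% names(res$causal)))
    expect_equal(res$causal$r2_mqtl, res$triangles$r2_mqtl)
    expect_equal(res$causal$r2_eqtl, res$triangles$r2_eqtl)
    expect_equal(res$causal$r2_exprmet, res$triangles$r2_exprmet)
    expect_true(any(res$causal$best_in_locus))
  }
  expect_equal(nrow(summarize_causal(res$triangles[0, ],
    study$discovery$genotypes, NULL, NULL)), 0L)
})
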