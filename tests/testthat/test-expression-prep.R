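make_expr <- function(values, detection_p = NULL, batch = NULL, qc = NULL) {
  p <- ncol(values)
  probes <- data.frame(probe_id = colnames(values),
    gene_symbol = paste0("G", seq_len(p)), chrom = "1",
    start = seq_len(p) * 1000L, end = seq_len(p) * 1000L + 50L)
  expression_matrix(values, probes, detection_p = detection_p, batch = batch,
    qc_features = qc)
}

test_that("detection filter is inclusive at the 5%-of-samples boundary", {
  set.seed(14)
  v <- matrix(rexp(100 * 3) + 1, 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  det <- matrix(1, 100, 3, dimnames = dimnames(v))
  det[1:5, 1] <- 0.01    # detected in exactly 5 of 100 -> retained
  det[1:4, 2] <- 0.01    # 4 of 100 -> dropped
  det[, 3] <- 0.001      # all -> retained
  f <- filter_expressed(make_expr(v, det))
  expect_setequal(colnames(f$values), c("a", "c"))
  expect_error(filter_expressed(make_expr(v, det[1:50, ])), "shape")
})

test_that("quantile normalization equalizes sample distributions and keeps ranks", {
  set.seed(15)
  v <- matrix(rexp(60 * 5) + 0.5, 60, 5, dimnames = list(NULL, paste0("p", 1:5)))
  qn <- quantile_normalize_log2(make_expr(v))
  pre <- 2^qn$values
  sorted <- apply(pre, 1, sort)
  expect_lt(max(apply(sorted, 1, function(r) diff(range(r)))), 1e-12)
  for (i in 1:5) {
    expect_equal(order(qn$values[i, ]), order(v[i, ]))
  }
  # two samples with identical values map to identical outputs
  v2 <- rbind(v, v[1, , drop = FALSE])
  qn2 <- quantile_normalize_log2(make_expr(v2))
  expect_equal(qn2$values[61, ], qn2$values[1, ], tolerance = 1e-12)
  expect_error(quantile_normalize_log2(make_expr(v - 5)), "positive")
})

test_that("sample outlier rules fire on constructed outliers and rarely under the null", {
  set.seed(16)
  n <- 500
  v <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("p", 1:30)))
  qc <- matrix(rnorm(n * 4), n, 4)
  det <- matrix(0.01, n, 30)
  rep0 <- flag_sample_outliers(make_expr(v, det, qc = qc))
  expect_lt(mean(rep0$euclid_outlier), 0.02)
  expect_lt(mean(rep0$qc_outlier), 0.02)
  expect_equal(mean(rep0$count_outlier), 0)
  # one sample shifted +10 SD on all probes
  v2 <- v; v2[7, ] <- v2[7, ] + 10
  rep1 <- flag_sample_outliers(make_expr(v2, det, qc = qc))
  expect_true(rep1$euclid_outlier[7])
  # a sample expressing half as many probes
  det2 <- det; det2[9, 1:15] <- 0.9
  rep2 <- flag_sample_outliers(make_expr(v, det2, qc = qc))
  expect_true(rep2$count_outlier[9])
})

test_that("batch adjustment removes a planted offset; single batch is identity", {
  set.seed(17)
  n <- 200
  batch <- rep(1:2, each = n / 2)
  v <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("p", 1:10)))
  v[batch == 2, ] <- v[batch == 2, ] + 2
  adj <- adjust_batch(make_expr(v, batch = batch), mode = "meanscale")
  dmeans <- colMeans(adj$values[batch == 1, ]) - colMeans(adj$values[batch == 2, ])
  se2 <- apply(adj$values, 2, function(col) {
    sqrt(var(col[batch == 1]) / sum(batch == 1) + var(col[batch == 2]) / sum(batch == 2))
  })
  expect_true(all(abs(dmeans) < 3 * se2))
  one <- adjust_batch(make_expr(v, batch = rep(1, n)), mode = "meanscale")
  expect_equal(one$values, v, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(adjust_batch(make_expr(v, batch = c(1, rep(2, n - 1)))), "single sample")
  # eb with infinite prior precision: all probes get their batch's average correction
  eb0 <- adjust_batch(make_expr(v, batch = batch), mode = "eb", prior_var = 0)
  shift <- v - eb0$values
  per_probe_shift <- colMeans(shift[batch == 2, , drop = FALSE]) -
    colMeans(shift[batch == 1, , drop = FALSE])
  expect_lt(diff(range(per_probe_shift)), 0.3)  # near-equal corrections
  eb <- adjust_batch(make_expr(v, batch = batch), mode = "eb")
  dm_eb <- colMeans(eb$values[batch == 1, ]) - colMeans(eb$values[batch == 2, ])
  expect_lt(max(abs(dm_eb)), 1)
})

test_that("residualization is orthogonal, idempotent, and kills planted covariate effects", {
  set.seed(18)
  n <- 150
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  v <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("p", 1:8)))
  v[, 3] <- v[, 3] + 1.0 * C[, "age"]
  E <- residualize_expression(make_expr(v), C, n_pcs = 3)
  for (j in 1:8) {
    expect_lt(abs(cor(E$values[, j], C[, "age"])), 1e-8)
    expect_lt(abs(cor(E$values[, j], C[, "sex"])), 1e-8)
  }
  f <- fit_ols(E$values[, 3], C[, "age"])
  expect_lt(abs(f$t), 1e-6)
  # idempotence (residualizing again changes nothing materially)
  E2 <- residualize_expression(E, C, n_pcs = 0)
  expect_equal(E2$values, E$values, tolerance = 1e-10)
  # n_pcs = 0 and no covariates = probe centering
  E3 <- residualize_expression(make_expr(v), NULL, n_pcs = 0)
  expect_equal(E3$values, sweep(v, 2, colMeans(v)), tolerance = 1e-12,
    ignore_attr = TRUE)
  # collinear regressors are dropped with a warning
  expect_warning(
    residualize_expression(make_expr(v), cbind(C, age2 = C[, "age"]), n_pcs = 0),
    "collinear")
})
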