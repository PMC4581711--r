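# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A small two-cohort study with the default planted effects, cached.
tiny_study <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- simulate_study(sim_config(seed = 42,
      n_discovery = 400, n_replication = 200))
  }
  .fixture_env$tiny
}

# The tiny study run through the full pipeline (reduced permutation
# counts), cached.
tiny_pipeline <- function() {
  if (is.null(.fixture_env$tiny_res)) {
    cfg <- default_config(n_perm_mqtl = 30L, n_perm_bh_check = 5L,
      n_perm_triangle = 5L, seed = 42L)
    .fixture_env$tiny_res <- suppressMessages(run_pipeline(tiny_study(), cfg))
  }
  .fixture_env$tiny_res
}

# Independent OLS oracle: explicit normal equations, no shared code with
# fit_ols / assoc_scan.
ols_oracle <- function(y, x, C = NULL) {
  X <- cbind(1, x, C)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  list(beta = beta[2], se = sqrt(covb[2, 2]), df = df)
}

# Independent greedy-pruning oracle: literal enumeration of the rule.
prune_oracle <- function(minp, r2mat) {
  remaining <- order(minp)
  kept <- integer(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    kept <- c(kept, best)
    remaining <- remaining[r2mat[best, remaining] < 0.3]
  }
  kept
}

random_panel <- function(values, kinds = "raw") {
  q <- ncol(values)
  defs <- data.frame(name = colnames(values), kind = rep(kinds, length.out = q),
    numerator = "", denominator = "", lod = NA_real_)
  metabolite_panel(values, defs)
}
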