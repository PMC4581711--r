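#' Synthetic study configuration
#'
#' Defines the simulated two-cohort multi-omics study: cohort sizes, the
#' SNP panel (LD blocks drawn from founder-haplotype pools), expression
#' probes with batch structure, a targeted metabolite panel with detection
#' limits, and the table of planted effects. The defaults describe the
#' study conditions every downstream test and the acceptance run use:
#' a 2000-sample discovery cohort, a 1000-sample replication cohort, 300
#' SNPs in blocks of 5 (20 founder haplotypes per block), 120 probes, 20
#' raw metabolites plus derived ratios/sums, and 20 planted effects.
#'
#' @param ... named overrides of the defaults.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_discovery = 2000L,
    n_replication = 1000L,
    n_snps = 300L,
    n_probes = 120L,
    n_metabolites = 20L,
    ld_block_size = 5L,
    haplotype_pool = 20L,
    maf_range = c(0.05, 0.5),
    dose_noise_sd = 0.05,   # imputation-like dosage noise
    batch_count = 3L,
    batch_shift_sd = 0.3,
    lod_quantile = 0.05,    # below-LOD fraction for ordinary metabolites
    high_lod_quantile = 0.30,  # for the designated poorly-detected columns
    n_high_lod = 2L,
    n_unexpressed = 6L,     # probes failing the detection filter
    rep_drop_frac = 0.10,   # SNPs absent from the replication panel
    covariate_age_effect = 0.01,
    covariate_sex_effect = 0.2,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown sim_config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_discovery >= 1, cfg$n_replication >= 1, cfg$n_snps >= 1,
    cfg$n_probes >= 1, cfg$n_metabolites >= 1, cfg$ld_block_size >= 1,
    cfg$haplotype_pool >= 2)
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must be a sub-interval of (0, 0.5]")
  }
  structure(cfg, class = "sim_config")
}

snp_label <- function(block, j) sprintf("b%02ds%d", block, j)

# Genome layout: blocks cycle over 10 chromosomes; same-chromosome blocks
# sit 5 Mb apart; SNPs within a block are 10 kb apart (so within-block
# neighbours fall inside the +/-50 kb proxy window).
snp_layout <- function(n_snps, ld_block_size) {
  block <- rep(seq_len(ceiling(n_snps / ld_block_size)), each = ld_block_size)[seq_len(n_snps)]
  within <- unlist(lapply(table(block), seq_len), use.names = FALSE)
  chrom <- as.character(((block - 1L) %% 10L) + 1L)
  pos <- 1000000L + ((block - 1L) %/% 10L) * 5000000L + (within - 1L) * 10000L
  data.frame(snp_id = snp_label(block, within), block = block,
    chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate a genotype gene-dose matrix with block LD
#'
#' SNPs come in blocks; within a block every individual draws two
#' haplotypes from a shared pool of founder haplotypes (blocks are
#' independent), so within-block LD is controlled by the pool and
#' across-block LD is zero in expectation. In every block of size >= 2 the
#' second SNP is a copy of the first's haplotype column (a built-in
#' near-perfect proxy, r2 ~ 1 up to dosage noise). Doses are allele counts
#' perturbed by truncated Gaussian noise to mimic imputation; the `info`
#' field is `1 - noise variance / dose variance`.
#'
#' @param n number of individuals (>= 2).
#' @param cfg a [sim_config()].
#' @param pools founder-haplotype pools from a previous call (to share the
#'   SNP panel across cohorts); generated when `NULL`.
#' @param seed optional RNG seed.
#' @param sample_prefix prefix for generated sample ids.
#' @return a [genotype_matrix()]; the pools are attached as
#'   `attr(, "pools")` and the block index as a `block` column in `$snps`.
#' @export
simulate_genotypes <- function(n, cfg = sim_config(), pools = NULL,
                               seed = NULL, sample_prefix = "D") {
  if (n < 2) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  lay <- snp_layout(cfg$n_snps, cfg$ld_block_size)
  blocks <- split(seq_len(cfg$n_snps), lay$block)
  if (is.null(pools)) {
    pools <- lapply(blocks, function(idx) {
      bsize <- length(idx)
      maf <- stats::runif(bsize, cfg$maf_range[1], cfg$maf_range[2])
      k <- pmin(pmax(1L, round(maf * cfg$haplotype_pool)),
        floor(cfg$haplotype_pool / 2))
      H <- vapply(k, function(kk) {
        col <- numeric(cfg$haplotype_pool)
        col[sample.int(cfg$haplotype_pool, kk)] <- 1
        col
      }, numeric(cfg$haplotype_pool))
      if (bsize >= 2) H[, 2] <- H[, 1]  # built-in proxy pair
      H
    })
  }
  doses <- matrix(0, n, cfg$n_snps)
  true_freq <- numeric(cfg$n_snps)
  for (b in seq_along(blocks)) {
    H <- pools[[b]]
    i1 <- sample.int(nrow(H), n, replace = TRUE)
    i2 <- sample.int(nrow(H), n, replace = TRUE)
    d <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
    true_freq[blocks[[b]]] <- colMeans(d) / 2
    doses[, blocks[[b]]] <- d
  }
  noisy <- pmin(pmax(doses + stats::rnorm(length(doses), 0, cfg$dose_noise_sd), 0), 2)
  v <- apply(noisy, 2, stats::var)
  info <- pmin(pmax(1 - cfg$dose_noise_sd^2 / pmax(v, 1e-12), 0), 1)
  snps <- data.frame(lay,
    allele_ref = "A", allele_alt = "G",
    maf = pmin(true_freq, 1 - true_freq),
    info = info, stringsAsFactors = FALSE)
  rownames(noisy) <- sprintf("%s%04d", sample_prefix, seq_len(n))
  colnames(noisy) <- snps$snp_id
  G <- genotype_matrix(noisy, snps[, c("snp_id", "chrom", "pos", "allele_ref",
    "allele_alt", "maf", "info")])
  G$snps$block <- snps$block
  attr(G, "pools") <- pools
  G
}

#' Simulate covariates
#'
#' Age ~ N(60, 10^2), sex ~ Bernoulli(0.5), and three synthetic genetic
#' principal components ~ N(0, 1), mirroring the structure (not the
#' confounding) of a cohort adjustment set.
#'
#' @param sample_ids character vector of sample ids.
#' @param seed optional RNG seed.
#' @return a [covariate_table()].
#' @export
simulate_covariates <- function(sample_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(sample_ids)
  df <- data.frame(
    age = stats::rnorm(n, 60, 10),
    sex = stats::rbinom(n, 1, 0.5),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
    row.names = sample_ids)
  covariate_table(df)
}

#' Default planted-effect table
#'
#' Twenty planted effects: six direct SNP-to-metabolite effects, five cis
#' and two trans SNP-to-probe effects, four probe-to-metabolite effects,
#' and three mediated chains (SNP -> cis probe -> metabolite, no direct
#' SNP term) marked by `snp_probe_metab_mediated` rows tying a
#' `snp_probe_cis` entry to a `probe_metab` entry. Mediated-chain effects
#' (0.8 SD/dose, 0.5 SD/SD) are strong enough that the induced
#' SNP-metabolite association clears the 1e-7 discovery cut-off at
#' n = 2000.
#'
#' @param cfg a [sim_config()].
#' @return data frame with columns `kind`, `snp_id`, `probe_id`,
#'   `metabolite`, `effect`.
#' @export
default_truth <- function(cfg = sim_config()) {
  lead <- function(b) snp_label(b, 1L)
  pr <- function(k) sprintf("P%03d", k)
  mb <- function(k) sprintf("M%02d", k)
  rbind(
    data.frame(kind = "snp_metab_direct", snp_id = lead(c(1:5, 12)), probe_id = NA,
      metabolite = mb(1:6), effect = c(0.5, 0.45, 0.4, 0.35, 0.3, 0.3)),
    data.frame(kind = "snp_probe_cis", snp_id = lead(7:11), probe_id = pr(1:5),
      metabolite = NA, effect = c(0.8, 0.8, 0.8, 0.5, 0.5)),
    data.frame(kind = "snp_probe_trans", snp_id = lead(12:13), probe_id = pr(6:7),
      metabolite = NA, effect = c(0.6, 0.5)),
    data.frame(kind = "probe_metab", snp_id = NA, probe_id = pr(c(1:3, 8)),
      metabolite = mb(7:10), effect = c(0.5, 0.5, 0.5, 0.3)),
    data.frame(kind = "snp_probe_metab_mediated", snp_id = lead(7:9),
      probe_id = pr(1:3), metabolite = mb(7:9), effect = NA)
  )
}

check_truth <- function(truth, snp_ids, probe_ids, metab_names) {
  bad_s <- setdiff(stats::na.omit(truth$snp_id), snp_ids)
  bad_p <- setdiff(stats::na.omit(truth$probe_id), probe_ids)
  bad_m <- setdiff(stats::na.omit(truth$metabolite), metab_names)
  if (length(c(bad_s, bad_p, bad_m)) > 0) {
    stop("truth table references unknown ids: ",
      paste(c(bad_s, bad_p, bad_m), collapse = ", "))
  }
  med <- truth[truth$kind == "snp_probe_metab_mediated", , drop = FALSE]
  for (i in seq_len(nrow(med))) {
    has_sp <- any(truth$kind %in% c("snp_probe_cis", "snp_probe_trans") &
      truth$snp_id == med$snp_id[i] & truth$probe_id == med$probe_id[i], na.rm = TRUE)
    has_pm <- any(truth$kind == "probe_metab" &
      truth$probe_id == med$probe_id[i] & truth$metabolite == med$metabolite[i],
      na.rm = TRUE)
    if (!has_sp || !has_pm) {
      stop("mediated entry ", i, " lacks its snp_probe or probe_metab component")
    }
  }
  invisible(truth)
}

#' Simulate an expression matrix with planted cis/trans effects
#'
#' Latent biological probe value = sum of planted per-dose effects x dose
#' plus N(0, 1) noise; the measured intensity additionally carries a
#' per-(batch, probe) Gaussian shift and is mapped to a positive raw scale
#' as `2^(latent + shift + baseline)`. Probes with a planted cis effect are
#' placed within 1 Mb of their SNP, trans probes on another chromosome.
#' The last `n_unexpressed` probes are background probes whose detection p
#' values exceed the detection cut-off in (almost) all samples.
#'
#' @param G a [genotype_matrix()].
#' @param truth planted-effect table (see [default_truth()]).
#' @param cfg a [sim_config()].
#' @param seed optional RNG seed.
#' @return an [expression_matrix()] (raw intensity scale) with
#'   `detection_p`, `batch`, `qc_features`, and the latent biological
#'   matrix attached as `attr(, "latent_bio")`.
#' @export
simulate_expression <- function(G, truth, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G$doses)
  p <- cfg$n_probes
  probe_ids <- sprintf("P%03d", seq_len(p))
  # default scatter layout, then relocate planted cis/trans probes
  chrom <- as.character(((seq_len(p) - 1L) %% 10L) + 1L)
  center <- 2500000 + ((seq_len(p) - 1L) %/% 10L) * 4000000
  eff <- truth[truth$kind %in% c("snp_probe_cis", "snp_probe_trans"), , drop = FALSE]
  check_truth(truth, G$snps$snp_id, probe_ids, unique(stats::na.omit(truth$metabolite)))
  latent <- matrix(stats::rnorm(n * p), n, p)
  for (i in seq_len(nrow(eff))) {
    js <- match(eff$snp_id[i], G$snps$snp_id)
    jp <- match(eff$probe_id[i], probe_ids)
    latent[, jp] <- latent[, jp] + eff$effect[i] * G$doses[, js]
    if (eff$kind[i] == "snp_probe_cis") {
      chrom[jp] <- G$snps$chrom[js]
      center[jp] <- G$snps$pos[js] + 200000
    } else {
      alt <- setdiff(as.character(1:10), G$snps$chrom[js])[1]
      chrom[jp] <- alt
      center[jp] <- G$snps$pos[js]
    }
  }
  # consistency guard: planted cis probes must lie within the cis window
  cis <- eff[eff$kind == "snp_probe_cis", , drop = FALSE]
  for (i in seq_len(nrow(cis))) {
    js <- match(cis$snp_id[i], G$snps$snp_id)
    jp <- match(cis$probe_id[i], probe_ids)
    if (chrom[jp] != G$snps$chrom[js] ||
        abs(center[jp] - G$snps$pos[js]) > 1000000) {
      stop("internal consistency error: cis probe ", probe_ids[jp],
        " placed > 1 Mb from its SNP")
    }
  }
  batch <- rep(seq_len(cfg$batch_count), length.out = n)
  shift <- matrix(stats::rnorm(cfg$batch_count * p, 0, cfg$batch_shift_sd),
    cfg$batch_count, p)
  baseline <- rep(8, p)
  unexpr <- if (cfg$n_unexpressed > 0) (p - cfg$n_unexpressed + 1L):p else integer(0)
  if (length(intersect(unexpr, match(stats::na.omit(c(truth$probe_id)), probe_ids))) > 0) {
    stop("planted effects may not involve unexpressed probes")
  }
  baseline[unexpr] <- 2
  intensity <- 2^(latent + shift[batch, , drop = FALSE] +
    matrix(baseline, n, p, byrow = TRUE))
  det <- matrix(stats::runif(n * p, 0, 0.04), n, p)
  det[, unexpr] <- stats::runif(n * length(unexpr), 0.06, 1)
  probes <- data.frame(probe_id = probe_ids,
    gene_symbol = sprintf("G%03d", seq_len(p)),
    chrom = chrom, start = round(center) - 500L, end = round(center) + 500L,
    stringsAsFactors = FALSE)
  qc <- matrix(stats::rnorm(n * 5), n, 5,
    dimnames = list(rownames(G$doses), paste0("qc", 1:5)))
  dimnames(intensity) <- list(rownames(G$doses), probe_ids)
  dimnames(det) <- dimnames(intensity)
  E <- expression_matrix(intensity, probes, detection_p = det, batch = batch,
    qc_features = qc)
  dimnames(latent) <- dimnames(intensity)
  attr(E, "latent_bio") <- latent
  E
}

#' Simulate a raw-scale metabolite panel
#'
#' Latent quantity = planted direct SNP effects x dose + planted probe
#' effects x biological expression + covariate effects + N(0, 1) noise;
#' the raw concentration is `exp(latent)` (positively skewed, so the
#' arsinh transform downstream is meaningful). Per column, readings below
#' the column's LOD quantile are flagged below-LOD and recorded missing;
#' the last `n_high_lod` columns use the high LOD quantile so they exceed
#' the 20% dichotomization rule.
#'
#' @param G a [genotype_matrix()].
#' @param E an [expression_matrix()] carrying `attr(, "latent_bio")`
#'   (mediated effects act through the biological expression component,
#'   not through batch artifacts).
#' @param C a [covariate_table()] with `age` and `sex`.
#' @param truth planted-effect table.
#' @param cfg a [sim_config()].
#' @param seed optional RNG seed.
#' @return a raw-stage [metabolite_panel()] holding the raw metabolites;
#'   ratio/sum definitions are attached as `attr(, "pending_defs")`.
#' @export
simulate_metabolites <- function(G, E, C, truth, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G$doses)
  q <- cfg$n_metabolites
  metab_names <- sprintf("M%02d", seq_len(q))
  bio <- attr(E, "latent_bio")
  if (is.null(bio)) stop("expression matrix lacks the latent biological component")
  latent <- matrix(stats::rnorm(n * q), n, q)
  dir_eff <- truth[truth$kind == "snp_metab_direct", , drop = FALSE]
  for (i in seq_len(nrow(dir_eff))) {
    jm <- match(dir_eff$metabolite[i], metab_names)
    js <- match(dir_eff$snp_id[i], G$snps$snp_id)
    latent[, jm] <- latent[, jm] + dir_eff$effect[i] * G$doses[, js]
  }
  pm_eff <- truth[truth$kind == "probe_metab", , drop = FALSE]
  for (i in seq_len(nrow(pm_eff))) {
    jm <- match(pm_eff$metabolite[i], metab_names)
    jp <- match(pm_eff$probe_id[i], colnames(bio))
    latent[, jm] <- latent[, jm] + pm_eff$effect[i] * bio[, jp]
  }
  # covariate effects on alternating columns
  affected <- seq_len(q) %% 2L == 1L
  latent[, affected] <- latent[, affected] +
    cfg$covariate_age_effect * (C$data$age - 60) +
    cfg$covariate_sex_effect * C$data$sex
  raw <- exp(latent)
  lodq <- rep(cfg$lod_quantile, q)
  if (cfg$n_high_lod > 0) lodq[(q - cfg$n_high_lod + 1L):q] <- cfg$high_lod_quantile
  below <- matrix(FALSE, n, q)
  lod <- numeric(q)
  for (j in seq_len(q)) {
    lod[j] <- stats::quantile(raw[, j], lodq[j], names = FALSE)
    below[, j] <- raw[, j] < lod[j]
    raw[below[, j], j] <- NA
  }
  dimnames(raw) <- list(rownames(G$doses), metab_names)
  dimnames(below) <- dimnames(raw)
  defs <- data.frame(name = metab_names, kind = "raw", numerator = "",
    denominator = "", lod = lod, stringsAsFactors = FALSE)
  panel <- metabolite_panel(raw, defs, below_lod = below, stage = "raw")
  attr(panel, "pending_defs") <- default_derived_defs()
  panel
}

#' Default derived-quantity definitions (two ratios, one sum)
#' @return data frame in the definitions-TSV layout.
#' @export
default_derived_defs <- function() {
  data.frame(
    name = c("RAT1", "RAT2", "ACTOT"),
    kind = c("ratio", "ratio", "sum"),
    numerator = c("M15", "M16+M17", "M11+M12+M13"),
    denominator = c("M16", "M18", ""),
    lod = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate a two-cohort study with shared ground truth
#'
#' Generates a discovery and a replication cohort that share the SNP panel
#' (same founder-haplotype pools) and the same planted effects but consist
#' of independent individuals. A configurable fraction of SNPs is removed
#' from the replication panel to exercise the proxy search. Replication
#' covariates keep age and sex only (the replication analysis adjusts for
#' fewer covariates than discovery).
#'
#' @param cfg a [sim_config()].
#' @param truth planted-effect table; [default_truth()] when `NULL`.
#' @return list with `discovery` and `replication` bundles (each a list of
#'   `genotypes`, `expression`, `metabolites`, `covariates`) and `truth`.
#' @export
simulate_study <- function(cfg = sim_config(), truth = NULL) {
  set.seed(cfg$seed)
  if (is.null(truth)) truth <- default_truth(cfg)
  G_d <- simulate_genotypes(cfg$n_discovery, cfg, sample_prefix = "D")
  C_d <- simulate_covariates(G_d$sample_ids)
  E_d <- simulate_expression(G_d, truth, cfg)
  M_d <- simulate_metabolites(G_d, E_d, C_d, truth, cfg)
  pools <- attr(G_d, "pools")
  G_r <- simulate_genotypes(cfg$n_replication, cfg, pools = pools,
    sample_prefix = "R")
  C_r <- simulate_covariates(G_r$sample_ids)
  E_r <- simulate_expression(G_r, truth, cfg)
  M_r <- simulate_metabolites(G_r, E_r, C_r, truth, cfg)
  # replication panel drops a fraction of SNPs, never the built-in proxies
  if (cfg$rep_drop_frac > 0) {
    n_drop <- floor(cfg$rep_drop_frac * cfg$n_snps)
    droppable <- which(!grepl("s2$", G_r$snps$snp_id))
    drop <- sample(droppable, min(n_drop, length(droppable)))
    if (length(drop) > 0) {
      keep <- setdiff(seq_len(cfg$n_snps), drop)
      G_r$doses <- G_r$doses[, keep, drop = FALSE]
      G_r$snps <- G_r$snps[keep, , drop = FALSE]
    }
  }
  check_truth(truth, G_d$snps$snp_id, E_d$probes$probe_id, colnames(M_d$values))
  list(
    discovery = list(genotypes = G_d, expression = E_d, metabolites = M_d,
      covariates = C_d),
    replication = list(genotypes = G_r, expression = E_r, metabolites = M_r,
      covariates = C_r),
    truth = truth
  )
}
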