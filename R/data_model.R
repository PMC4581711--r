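#' Genotype matrix of imputed gene doses
#'
#' Container for a samples x SNPs matrix of gene doses (expected counts of
#' the alternative allele, each in `[0, 2]`) together with per-SNP metadata.
#'
#' @param doses numeric matrix, samples in rows, SNPs in columns; row names
#'   are sample ids, column names SNP ids.
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_ref`, `allele_alt`, `maf` (in `[0, 0.5]`) and `info` (in `[0, 1]`),
#'   one row per dose column, in column order.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(doses, snps) {
  doses <- as.matrix(doses)
  storage.mode(doses) <- "double"
  snps <- as.data.frame(snps)
  req <- c("snp_id", "chrom", "pos", "allele_ref", "allele_alt", "maf", "info")
  if (!all(req %in% names(snps))) {
    stop("snps must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(snps) != ncol(doses)) stop("one snps row per dose column required")
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id: ", snps$snp_id[duplicated(snps$snp_id)][1])
  }
  if (is.null(colnames(doses))) colnames(doses) <- snps$snp_id
  if (!identical(colnames(doses), as.character(snps$snp_id))) {
    stop("dose column names must equal snps$snp_id in order")
  }
  if (is.null(rownames(doses))) {
    rownames(doses) <- paste0("S", seq_len(nrow(doses)))
  }
  bad <- which(!is.na(doses) & (doses < 0 | doses > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("dose outside [0,2] at sample '%s', snp '%s' (value %g)",
      rownames(doses)[bad[1, 1]], colnames(doses)[bad[1, 2]],
      doses[bad[1, 1], bad[1, 2]]))
  }
  if (any(snps$pos < 1)) stop("pos must be >= 1")
  if (any(snps$maf < 0 | snps$maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (any(snps$info < 0 | snps$info > 1)) stop("info must lie in [0, 1]")
  structure(list(sample_ids = rownames(doses), snps = snps, doses = doses),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d chromosomes)\n",
    nrow(x$doses), ncol(x$doses), length(unique(x$snps$chrom))))
  invisible(x)
}

#' Expression matrix with probe annotation
#'
#' @param values numeric matrix, samples x probes.
#' @param probes data frame with `probe_id`, `gene_symbol`, `chrom`,
#'   `start`, `end`; a `center` column (`(start + end) / 2`, possibly
#'   half-integral) is added if absent.
#' @param detection_p optional matrix of detection p values (same shape).
#' @param batch optional per-sample batch labels.
#' @param qc_features optional per-sample numeric QC matrix.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probes, detection_p = NULL,
                              batch = NULL, qc_features = NULL) {
  values <- as.matrix(values)
  probes <- as.data.frame(probes)
  req <- c("probe_id", "gene_symbol", "chrom", "start", "end")
  if (!all(req %in% names(probes))) {
    stop("probes must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(probes) != ncol(values)) stop("one probes row per value column required")
  if (any(probes$start > probes$end)) stop("probe start must be <= end")
  if (is.null(probes$center)) probes$center <- (probes$start + probes$end) / 2
  if (is.null(colnames(values))) colnames(values) <- probes$probe_id
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (!is.null(detection_p) && !all(dim(detection_p) == dim(values))) {
    stop("detection_p must match the value matrix shape")
  }
  if (!is.null(batch) && length(batch) != nrow(values)) {
    stop("one batch label per sample required")
  }
  structure(list(sample_ids = rownames(values), probes = probes,
    values = values, detection_p = detection_p, batch = batch,
    qc_features = qc_features), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probes\n",
    nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Metabolite panel
#'
#' Samples x quantities with per-quantity definitions (raw measurements,
#' ratios, sums, and dichotomized below/above-detection indicators), a
#' below-limit-of-detection flag matrix and a preprocessing-stage marker.
#'
#' @param values numeric matrix, samples x quantities; NA marks missing.
#' @param defs data frame with `name`, `kind` (one of raw/ratio/sum/
#'   dichotomized), `numerator`, `denominator` (component raw names joined
#'   by `+`, empty for raw), and optional `lod`.
#' @param below_lod logical matrix flagging readings below the detection
#'   limit (defaults to all-FALSE).
#' @param stage preprocessing stage: raw, derived, dichotomized,
#'   transformed or masked. Stages must be applied in that order.
#' @return an object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(values, defs, below_lod = NULL, stage = "raw") {
  values <- as.matrix(values)
  defs <- as.data.frame(defs, stringsAsFactors = FALSE)
  req <- c("name", "kind")
  if (!all(req %in% names(defs))) stop("defs must have columns name, kind")
  if (is.null(defs$numerator)) defs$numerator <- ""
  if (is.null(defs$denominator)) defs$denominator <- ""
  if (is.null(defs$lod)) defs$lod <- NA_real_
  if (!all(defs$kind %in% c("raw", "ratio", "sum", "dichotomized"))) {
    stop("unknown metabolite kind")
  }
  if (nrow(defs) != ncol(values)) stop("one defs row per value column required")
  if (is.null(colnames(values))) colnames(values) <- defs$name
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(below_lod)) {
    below_lod <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (!all(dim(below_lod) == dim(values))) stop("below_lod must match values shape")
  stage <- match.arg(stage, c("raw", "derived", "dichotomized", "transformed", "masked"))
  dich <- defs$kind == "dichotomized"
  if (any(dich)) {
    v <- values[, dich, drop = FALSE]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      stop("dichotomized columns may contain only 0, 1 or NA")
    }
  }
  structure(list(sample_ids = rownames(values), defs = defs, values = values,
    below_lod = below_lod, stage = stage), class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("metabolite_panel: %d samples x %d quantities (stage: %s)\n",
    nrow(x$values), ncol(x$values), x$stage))
  cat("  kinds:", paste(names(table(x$defs$kind)), table(x$defs$kind),
    sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Covariate table
#'
#' @param data data frame of numeric covariates (binary covariates coded
#'   0/1), row names = sample ids.
#' @param types optional named character vector tagging each column
#'   `"continuous"` or `"binary"`; inferred (columns containing only 0/1
#'   are binary) when omitted.
#' @return an object of class `covariate_table`.
#' @export
covariate_table <- function(data, types = NULL) {
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("covariates must be numeric (code binary covariates 0/1)")
  }
  if (is.null(types)) {
    types <- vapply(data, function(v) {
      if (all(v %in% c(0, 1) | is.na(v))) "binary" else "continuous"
    }, character(1))
  }
  for (nm in names(types)[types == "binary"]) {
    if (!all(data[[nm]] %in% c(0, 1) | is.na(data[[nm]]))) {
      stop("binary covariate '", nm, "' contains values other than 0/1")
    }
  }
  if (is.null(rownames(data)) || identical(rownames(data), as.character(seq_len(nrow(data))))) {
    rownames(data) <- paste0("S", seq_len(nrow(data)))
  }
  structure(list(sample_ids = rownames(data), data = data, types = types),
    class = "covariate_table")
}

#' Default run configuration
#'
#' All analysis thresholds with their study defaults: discovery p cut-off
#' 1e-7, FDR level 5%, LD-pruning r-squared 0.3, proxy r-squared 0.8 within
#' a +/-50 kb window with imputation-info > 0.3, 1 Mb cis window, 1000
#' permutations for the mQTL null and 100 for the eQTL-threshold check and
#' the triangle null, 5-SD outlier interval and the strict >20% below-LOD
#' dichotomization rule.
#'
#' @param ... named overrides of any default.
#' @return an object of class `run_config` (a named list).
#' @export
default_config <- function(...) {
  cfg <- list(
    p_report = 1e-7,       # discovery-stage reporting cut-off
    fdr = 0.05,            # study-wide FDR level
    prune_r2 = 0.3,        # LD pruning threshold (exclusive: keep r2 < 0.3)
    proxy_r2 = 0.8,        # proxy qualification (strict: r2 > 0.8)
    proxy_window = 50000L, # +/- window for proxy search, bp
    info_min = 0.3,        # imputation-info floor for proxies (strict >)
    cis_window = 1000000L, # cis/trans split, inclusive, bp
    locus_merge_bp = 1000000L,
    n_perm_mqtl = 1000L,
    n_perm_bh_check = 100L,
    n_perm_triangle = 100L,
    outlier_k = 5,
    lod_frac = 0.20,       # strict: dichotomize when fraction below LOD > 0.20
    n_expr_pcs = 5L,
    detection_p_cut = 0.05,
    detection_sample_frac = 0.05,
    freeze_leads = FALSE,  # reuse observed lead set inside the triangle null
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
      "; valid keys: ", paste(names(cfg), collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config_values(cfg)
  structure(cfg, class = "run_config")
}

validate_config_values <- function(cfg) {
  chk01 <- c("fdr", "prune_r2", "proxy_r2", "info_min", "lod_frac",
    "detection_p_cut", "detection_sample_frac")
  for (k in chk01) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1) {
      stop("config key '", k, "' must lie in [0, 1]")
    }
  }
  if (cfg$p_report <= 0 || cfg$p_report > 1) stop("config key 'p_report' must lie in (0, 1]")
  for (k in c("proxy_window", "cis_window", "locus_merge_bp", "n_perm_mqtl",
    "n_perm_bh_check", "n_perm_triangle", "n_expr_pcs")) {
    if (cfg[[k]] < 0) stop("config key '", k, "' must be nonnegative")
  }
  if (cfg$outlier_k <= 0) stop("config key 'outlier_k' must be positive")
  invisible(cfg)
}

#' Load and validate a run configuration from YAML
#'
#' Missing keys take the study defaults (see [default_config()]); unknown
#' keys and out-of-range thresholds are rejected.
#'
#' @param path YAML file; an empty file yields the full default config.
#' @return a validated `run_config`.
#' @export
validate_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(default_config, vals)
}
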