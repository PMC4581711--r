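## eQTL mapping of validated lead SNPs, expression-metabolite association,
## association-triangle discovery with a permutation/Poisson null, and
## assembly of the significant-association network.

#' Classify a SNP-probe pair as cis or trans
#'
#' Cis iff the SNP and the probe center lie on the same chromosome and
#' `|snp pos - probe center| <= window_bp` ("not larger than 1 Mb" is
#' inclusive); trans otherwise (including different chromosomes at any
#' distance).
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors recycle).
#' @param probe_chrom,probe_center probe coordinates (center may be
#'   half-integral).
#' @param window_bp cis window (default 1 Mb, inclusive).
#' @return character vector `"cis"`/`"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, probe_chrom, probe_center,
                               window_bp = 1000000) {
  if (any(is.na(snp_chrom) | is.na(snp_pos) | is.na(probe_chrom) | is.na(probe_center))) {
    stop("missing coordinates in cis/trans classification")
  }
  ifelse(snp_chrom == probe_chrom & abs(snp_pos - probe_center) <= window_bp,
    "cis", "trans")
}

#' eQTL scan of lead SNPs against the prepared expression matrix
#'
#' One OLS per (lead SNP, probe); records are labeled cis or trans by the
#' 1 Mb rule and significance is decided within each layer by its own
#' Benjamini-Hochberg threshold at the given FDR.
#'
#' @param leads a `lead_snp_set` (or character vector of SNP ids).
#' @param G discovery [genotype_matrix()].
#' @param E prepared (residualized) [expression_matrix()].
#' @param covariates covariates for the eQTL model (e.g. genetic PCs);
#'   the expression matrix is typically already residualized, so this is
#'   often NULL.
#' @param fdr FDR level (default 0.05).
#' @param cis_window cis window in bp.
#' @return list with `records` (association records, layer `eqtl_cis` /
#'   `eqtl_trans`, logical `significant`), and `thresholds` from
#'   [bh_layer_thresholds()].
#' @export
run_eqtl_scan <- function(leads, G, E, covariates = NULL, fdr = 0.05,
                          cis_window = 1000000) {
  snp_ids <- if (inherits(leads, "lead_snp_set")) leads$lead_snps$snp_id else leads
  snp_ids <- intersect(snp_ids, G$snps$snp_id)
  if (length(snp_ids) == 0) {
    rec <- empty_records("eqtl")
    return(list(records = rec, thresholds = bh_layer_thresholds(numeric(0), numeric(0))))
  }
  X <- G$doses[, snp_ids, drop = FALSE]
  rec <- assoc_scan(X, E$values, covariates, layer = "eqtl")
  meta <- G$snps[match(rec$x_id, G$snps$snp_id), ]
  pm <- E$probes[match(rec$y_id, E$probes$probe_id), ]
  rec$layer <- paste0("eqtl_", classify_cis_trans(meta$chrom, meta$pos,
    pm$chrom, pm$center, cis_window))
  cis <- rec$layer == "eqtl_cis"
  thr <- bh_layer_thresholds(rec$p[cis], rec$p[!cis], fdr)
  rec$significant <- ifelse(cis, rec$p <= thr$cis & thr$cis > 0,
    rec$p <= thr$trans & thr$trans > 0)
  rec$significant[is.na(rec$p)] <- FALSE
  list(records = rec, thresholds = thr)
}

#' Expression-metabolite association on the triangle candidate grid
#'
#' Tests each eQTL-significant probe against the metabolites that are
#' mQTL-associated at the corresponding SNPs (the grid the triangle
#' search closes over), adjusting for the covariate set; BH within this
#' layer at the given FDR.
#'
#' @param probe_ids probes to test (eQTL-significant transcripts).
#' @param metab_names metabolites to test.
#' @param E prepared [expression_matrix()].
#' @param panel prepared [metabolite_panel()].
#' @param covariates covariate set.
#' @param fdr FDR level.
#' @return list with `records` (layer `expr_metab`, logical
#'   `significant`) and the BH `threshold`.
#' @export
run_expr_metab_scan <- function(probe_ids, metab_names, E, panel,
                                covariates = NULL, fdr = 0.05) {
  probe_ids <- intersect(probe_ids, colnames(E$values))
  metab_names <- intersect(metab_names, colnames(panel$values))
  if (length(probe_ids) == 0 || length(metab_names) == 0) {
    return(list(records = empty_records("expr_metab"), threshold = 0))
  }
  rec <- assoc_scan(E$values[, probe_ids, drop = FALSE],
    panel$values[, metab_names, drop = FALSE], covariates,
    layer = "expr_metab")
  q <- bh_qvalues(rec$p)
  rec$q <- q
  rec$significant <- !is.na(q) & q <= fdr
  thr <- if (any(rec$significant)) max(rec$p[rec$significant]) else 0
  list(records = rec, threshold = thr)
}

empty_records <- function(layer) {
  data.frame(x_id = character(), y_id = character(), layer = character(),
    beta = numeric(), se = numeric(), t = numeric(), p = numeric(),
    n = integer(), df = integer(), explained_var = numeric(),
    significant = logical(), stringsAsFactors = FALSE)
}

#' Build association triangles
#'
#' A triangle is a SNP significantly associated with both a probe and a
#' metabolite, whose probe is also significantly associated with that
#' metabolite. Strict mode follows the locus-wise rule: per locus take
#' the top SNP (minimal mQTL p), its best-associated metabolite, and that
#' SNP's significant eQTL probes; a triangle forms for each such probe
#' with a significant probe-metabolite edge. Exhaustive mode enumerates
#' every significant (SNP, probe, metabolite) closure.
#'
#' @param mqtl_sig significant mQTL records (must carry `locus_id` in
#'   strict mode).
#' @param eqtl_sig eQTL records with `significant`.
#' @param exprmet_sig expression-metabolite records with `significant`.
#' @param mode `"strict"` or `"exhaustive"`.
#' @return data frame of triangle records: ids, the three betas/p/
#'   explained variances and `cis_or_trans`.
#' @export
build_triangles <- function(mqtl_sig, eqtl_sig, exprmet_sig,
                            mode = c("strict", "exhaustive")) {
  mode <- match.arg(mode)
  eq <- eqtl_sig[eqtl_sig$significant, , drop = FALSE]
  em <- exprmet_sig[exprmet_sig$significant, , drop = FALSE]
  if (nrow(mqtl_sig) == 0 || nrow(eq) == 0 || nrow(em) == 0) {
    return(triangle_frame())
  }
  if (mode == "strict") {
    if (is.null(mqtl_sig$locus_id)) stop("strict mode needs locus_id on mQTL records")
    per_locus <- split(mqtl_sig, mqtl_sig$locus_id)
    cand <- do.call(rbind, lapply(per_locus, function(d) {
      top_snp <- d$x_id[which.min(d$p)]
      dd <- d[d$x_id == top_snp, , drop = FALSE]
      dd[which.min(dd$p), , drop = FALSE]       # best metabolite of top SNP
    }))
  } else {
    cand <- mqtl_sig
  }
  out <- lapply(seq_len(nrow(cand)), function(i) {
    s <- cand$x_id[i]; m <- cand$y_id[i]
    probes <- eq[eq$x_id == s, , drop = FALSE]
    if (nrow(probes) == 0) return(NULL)
    closed <- em[em$x_id %in% probes$y_id & em$y_id == m, , drop = FALSE]
    if (nrow(closed) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(closed)), function(k) {
      pe <- probes[probes$y_id == closed$x_id[k], , drop = FALSE][1, ]
      data.frame(snp_id = s, probe_id = pe$y_id, metabolite = m,
        cis_or_trans = sub("eqtl_", "", pe$layer),
        beta_mqtl = cand$beta[i], p_mqtl = cand$p[i], r2_mqtl = cand$explained_var[i],
        beta_eqtl = pe$beta, p_eqtl = pe$p, r2_eqtl = pe$explained_var,
        beta_exprmet = closed$beta[k], p_exprmet = closed$p[k],
        r2_exprmet = closed$explained_var[k],
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) triangle_frame() else { rownames(out) <- NULL; out }
}

triangle_frame <- function() {
  data.frame(snp_id = character(), probe_id = character(),
    metabolite = character(), cis_or_trans = character(),
    beta_mqtl = numeric(), p_mqtl = numeric(), r2_mqtl = numeric(),
    beta_eqtl = numeric(), p_eqtl = numeric(), r2_eqtl = numeric(),
    beta_exprmet = numeric(), p_exprmet = numeric(), r2_exprmet = numeric(),
    stringsAsFactors = FALSE)
}

#' Poisson tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, computed in log space
#' (`ppois(k - 1, lambda, lower.tail = FALSE)`; `k = 0` gives 1, and
#' `lambda = 0` gives 0 for any `k >= 1`).
#'
#' @param k_observed observed count (>= 0).
#' @param lambda_hat null mean (>= 0).
#' @return tail probability.
#' @export
poisson_tail_p <- function(k_observed, lambda_hat) {
  stopifnot(k_observed >= 0, lambda_hat >= 0)
  if (k_observed == 0) return(1)
  exp(stats::ppois(k_observed - 1, lambda_hat, lower.tail = FALSE, log.p = TRUE))
}

#' Assemble the significant-association network
#'
#' Nodes are typed (locus with/without triangles, cis gene, trans gene,
#' raw metabolite, metabolite ratio/sum/dichotomized trait); edges carry
#' their layer and explained-variance weight.
#'
#' @param mqtl_sig,eqtl_sig,exprmet_sig significant association records
#'   (eQTL/expr-metab records are filtered on `significant`).
#' @param panel the [metabolite_panel()] (for trait kinds).
#' @param E the [expression_matrix()] (for gene symbols).
#' @param triangles triangle records (marks loci carrying triangles).
#' @param lead_loci optional `lead_snps` table mapping SNPs to locus ids.
#' @return list with `nodes` and `edges` data frames for
#'   [write_network()].
#' @export
build_network <- function(mqtl_sig, eqtl_sig, exprmet_sig, panel, E,
                          triangles = triangle_frame(), lead_loci = NULL) {
  eq <- eqtl_sig[isTRUE_vec(eqtl_sig$significant), , drop = FALSE]
  em <- exprmet_sig[isTRUE_vec(exprmet_sig$significant), , drop = FALSE]
  edges <- rbind(
    if (nrow(mqtl_sig) > 0) data.frame(from = mqtl_sig$x_id, to = mqtl_sig$y_id,
      layer = "mqtl", explained_var = mqtl_sig$explained_var),
    if (nrow(eq) > 0) data.frame(from = eq$x_id, to = eq$y_id,
      layer = eq$layer, explained_var = eq$explained_var),
    if (nrow(em) > 0) data.frame(from = em$x_id, to = em$y_id,
      layer = "expr_metab", explained_var = em$explained_var))
  if (is.null(edges)) edges <- data.frame(from = character(), to = character(),
    layer = character(), explained_var = numeric())
  edges <- unique(edges)
  snp_nodes <- unique(c(mqtl_sig$x_id, eq$x_id))
  probe_nodes <- unique(c(eq$y_id, em$x_id))
  metab_nodes <- unique(c(mqtl_sig$y_id, em$y_id))
  role_snp <- ifelse(snp_nodes %in% triangles$snp_id, "locus_with_triangles", "locus")
  cis_probes <- unique(eq$y_id[eq$layer == "eqtl_cis"])
  role_probe <- ifelse(probe_nodes %in% cis_probes, "cis_gene", "trans_gene")
  kinds <- panel$defs$kind[match(metab_nodes, panel$defs$name)]
  role_metab <- c(raw = "raw_metabolite", ratio = "metabolite_ratio",
    sum = "metabolite_sum", dichotomized = "metabolite_dichotomized")[kinds]
  nodes <- data.frame(
    id = c(snp_nodes, probe_nodes, metab_nodes),
    role = c(role_snp, role_probe, unname(role_metab)),
    stringsAsFactors = FALSE)
  if (!is.null(lead_loci)) {
    nodes$locus_id <- lead_loci$locus_id[match(nodes$id, lead_loci$snp_id)]
  }
  list(nodes = nodes, edges = edges)
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x
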