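## Readers and writers for the pipeline's tabular dialect:
## tab-separated, UTF-8, "NA" for missing, first column "sample_id".

read_tsv_matrix <- function(path, what = "value") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
    na.strings = "NA")
  if (names(df)[1] != "sample_id") stop("first column of ", path, " must be 'sample_id'")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!is.na(m) & is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
    loc <- if (nrow(bad) > 0) {
      sprintf(" (sample '%s', column '%s')", ids[bad[1, 1]], colnames(m)[bad[1, 2]])
    } else ""
    stop("non-numeric ", what, " cell in ", path, loc)
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genotype gene-dose matrix
#'
#' TSV dialect: samples in rows (first column `sample_id`), SNP ids as the
#' remaining column names, doses in `[0, 2]`; SNP metadata comes from a
#' sidecar annotation TSV (`snp_id`, `chrom`, `pos`, `allele_ref`,
#' `allele_alt`, `maf`, `info`). VCF input is read through vcfR and uses
#' the DS dosage field when present, else the expected dose implied by GT.
#'
#' @param path genotype file.
#' @param format `"tsv"` or `"vcf"`.
#' @param annot_path SNP annotation TSV (required for `format = "tsv"`).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), annot_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (is.null(annot_path)) stop("annot_path is required for TSV genotypes")
    doses <- read_tsv_matrix(path, "dose")
    snps <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
    snps <- snps[match(colnames(doses), snps$snp_id), , drop = FALSE]
    if (anyNA(snps$snp_id)) stop("annotation missing for some dose columns")
    genotype_matrix(doses, snps)
  } else {
    read_genotypes_vcf(path)
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
    error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]))
    })
  }
  doses <- t(ds)  # vcfR gives variants x samples
  maf <- vapply(seq_len(ncol(doses)), function(j) {
    f <- mean(doses[, j], na.rm = TRUE) / 2
    min(f, 1 - f)
  }, numeric(1))
  snps <- data.frame(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
      paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_ref = fix$REF, allele_alt = fix$ALT,
    maf = maf, info = 1, stringsAsFactors = FALSE)
  colnames(doses) <- snps$snp_id
  genotype_matrix(doses, snps)
}

#' Write a genotype matrix (doses + annotation sidecar)
#' @param G a [genotype_matrix()].
#' @param path dose TSV path.
#' @param annot_path annotation TSV path.
#' @export
write_genotypes <- function(G, path, annot_path) {
  write_tsv_matrix(G$doses, path)
  utils::write.table(G$snps, annot_path, sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression matrix with BED-like probe annotation
#'
#' @param path expression TSV (samples x probes).
#' @param annot_path probe annotation TSV with columns `probe_id`, `chrom`,
#'   `start`, `end`, `gene_symbol` (1-based inclusive coordinates).
#' @param detection_path optional detection-p TSV of the same shape.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, annot_path, detection_path = NULL) {
  values <- read_tsv_matrix(path, "expression")
  probes <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  probes <- probes[match(colnames(values), probes$probe_id), , drop = FALSE]
  if (anyNA(probes$probe_id)) stop("probe annotation missing for some columns")
  det <- if (!is.null(detection_path)) read_tsv_matrix(detection_path, "detection p") else NULL
  expression_matrix(values, probes, detection_p = det)
}

#' @rdname read_expression
#' @param E an [expression_matrix()] to write.
#' @export
write_expression <- function(E, path, annot_path, detection_path = NULL) {
  write_tsv_matrix(E$values, path)
  utils::write.table(E$probes, annot_path, sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  if (!is.null(detection_path) && !is.null(E$detection_p)) {
    write_tsv_matrix(E$detection_p, detection_path)
  }
  invisible(path)
}

#' Read a metabolite panel with quantity definitions
#'
#' The definitions TSV mirrors the panel's quantity sheet: `name`, `kind`
#' (raw/ratio/sum/dichotomized), `numerator` and `denominator` (raw
#' component names joined by `+`), optional `lod`. Ratio/sum definitions
#' referencing unknown raw names are rejected.
#'
#' @param path metabolite value TSV (raw scale).
#' @param defs_path definitions TSV.
#' @param below_lod_path optional 0/1 TSV of below-detection flags.
#' @return a [metabolite_panel()].
#' @export
read_metabolites <- function(path, defs_path, below_lod_path = NULL) {
  values <- read_tsv_matrix(path, "metabolite")
  defs <- utils::read.delim(defs_path, stringsAsFactors = FALSE, na.strings = "NA")
  defs$numerator[is.na(defs$numerator)] <- ""
  defs$denominator[is.na(defs$denominator)] <- ""
  raw_names <- defs$name[defs$kind == "raw"]
  for (i in which(defs$kind %in% c("ratio", "sum"))) {
    comp <- unlist(split_components(c(defs$numerator[i], defs$denominator[i])))
    unknown <- setdiff(comp, raw_names)
    if (length(unknown) > 0) {
      stop("definition '", defs$name[i], "' references unknown raw name(s): ",
        paste(unknown, collapse = ", "))
    }
  }
  defs <- defs[order(match(defs$name, colnames(values), nomatch = nrow(defs) + 1L)), ]
  measured <- defs[defs$name %in% colnames(values), , drop = FALSE]
  derived <- defs[!defs$name %in% colnames(values), , drop = FALSE]
  bl <- if (!is.null(below_lod_path)) {
    m <- read_tsv_matrix(below_lod_path, "below-LOD flag") > 0
    m[, measured$name, drop = FALSE]
  } else NULL
  panel <- metabolite_panel(values[, measured$name, drop = FALSE], measured,
    below_lod = bl)
  attr(panel, "pending_defs") <- derived  # ratio/sum definitions to derive
  panel
}

split_components <- function(x) {
  lapply(x, function(s) {
    s <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    s[nzchar(s)]
  })
}

#' @rdname read_metabolites
#' @param panel a [metabolite_panel()] to write.
#' @export
write_metabolites <- function(panel, path, defs_path, below_lod_path = NULL) {
  write_tsv_matrix(panel$values, path)
  utils::write.table(panel$defs, defs_path, sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  if (!is.null(below_lod_path)) {
    write_tsv_matrix(panel$below_lod * 1, below_lod_path)
  }
  invisible(path)
}

#' Read a covariate table
#' @param path TSV with first column `sample_id` and numeric covariates.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(path) {
  m <- read_tsv_matrix(path, "covariate")
  covariate_table(as.data.frame(m))
}

#' @rdname read_covariates
#' @param C a [covariate_table()] to write.
#' @export
write_covariates <- function(C, path) {
  write_tsv_matrix(as.matrix(C$data), path)
}

#' Harmonize sample sets across omics layers
#'
#' Restricts every supplied object to the intersection of sample ids, in a
#' common (sorted-by-first-object) order. Every analysis set in the
#' pipeline is a complete-data intersection, never a union.
#'
#' @param ... named objects among [genotype_matrix()],
#'   [expression_matrix()], [metabolite_panel()] and [covariate_table()].
#' @return list of the harmonized objects plus `n` (intersection size).
#' @export
harmonize_samples <- function(...) {
  objs <- list(...)
  ids <- lapply(objs, function(o) o$sample_ids)
  common <- Reduce(intersect, ids)
  if (length(common) == 0) stop("empty sample intersection across inputs")
  common <- ids[[1]][ids[[1]] %in% common]  # keep first object's order
  dropped <- sum(vapply(ids, function(x) length(setdiff(x, common)), numeric(1)))
  if (dropped > 0) {
    message("harmonize_samples: intersection n = ", length(common),
      " (", dropped, " sample entries outside the intersection dropped)")
  }
  out <- lapply(objs, function(o) subset_samples(o, common))
  out$n <- length(common)
  out
}

subset_samples <- function(o, ids) {
  i <- match(ids, o$sample_ids)
  if (inherits(o, "genotype_matrix")) {
    o$doses <- o$doses[i, , drop = FALSE]
  } else if (inherits(o, "expression_matrix")) {
    o$values <- o$values[i, , drop = FALSE]
    if (!is.null(o$detection_p)) o$detection_p <- o$detection_p[i, , drop = FALSE]
    if (!is.null(o$batch)) o$batch <- o$batch[i]
    if (!is.null(o$qc_features)) o$qc_features <- o$qc_features[i, , drop = FALSE]
  } else if (inherits(o, "metabolite_panel")) {
    o$values <- o$values[i, , drop = FALSE]
    o$below_lod <- o$below_lod[i, , drop = FALSE]
  } else if (inherits(o, "covariate_table")) {
    o$data <- o$data[i, , drop = FALSE]
  } else {
    stop("unsupported object in harmonize_samples")
  }
  o$sample_ids <- ids
  o
}

#' Export the association network
#'
#' Writes the significant-association graph (loci, cis/trans genes, raw
#' metabolites and ratios as typed nodes; associations as edges weighted by
#' explained variance) as GraphML or JSON node-link.
#'
#' @param nodes data frame with `id` and `role` (locus, cis_gene,
#'   trans_gene, raw_metabolite, metabolite_ratio, ...).
#' @param edges data frame with `from`, `to`, `layer`, `explained_var`.
#' @param path output file.
#' @param format `"graphml"` or `"json"`.
#' @export
write_network <- function(nodes, edges, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (nrow(edges) > 0) {
    dangling <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(dangling) > 0) {
      stop("dangling edge endpoint(s): ", paste(dangling, collapse = ", "))
    }
    if (is.null(edges$explained_var) || is.null(edges$layer)) {
      stop("edges must carry explained_var and layer")
    }
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges) > 0) edges else data.frame(from = character(), to = character()),
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    jsonlite::write_json(list(nodes = nodes, links = edges), path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path file path.
#' @param format `"graphml"` or `"json"`.
#' @return list with `nodes` and `edges` data frames.
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::as_data_frame(g, what = "vertices")
    names(nodes)[names(nodes) == "name"] <- "id"
    edges <- igraph::as_data_frame(g, what = "edges")
    list(nodes = nodes, edges = edges)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    list(nodes = as.data.frame(x$nodes), edges = as.data.frame(x$links))
  }
}
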