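## Metabolite preprocessing: derive ratios/sums on the raw scale, apply the
## strict >20% below-detection dichotomization, the arsinh transform and the
## single-pass mean +/- 5 SD outlier rule — in that order only.

stage_rank <- c(raw = 1, derived = 2, dichotomized = 3, transformed = 4, masked = 5)

require_stage <- function(panel, allowed, op) {
  if (!panel$stage %in% allowed) {
    stop(op, " requires a panel at stage ", paste(allowed, collapse = "/"),
      " (got '", panel$stage, "'); the pipeline order is ",
      "derive -> dichotomize -> transform -> mask")
  }
}

#' Derive ratio and sum quantities on the raw scale
#'
#' Ratios are `(sum of numerator components) / (sum of denominator
#' components)` and sums the plain component total, both computed on the
#' raw concentration scale before any transformation (the arsinh of a
#' ratio is not a difference of arsinhs, so the order matters). A derived
#' value is missing whenever any component is missing; a zero denominator
#' yields a missing value and is counted in the attached report.
#'
#' @param panel a raw-stage [metabolite_panel()].
#' @param defs definitions of the derived quantities (data frame with
#'   `name`, `kind` in ratio/sum, `numerator`, `denominator` as `+`-joined
#'   raw names); defaults to the panel's pending definitions.
#' @return the panel extended by the derived columns, at stage "derived";
#'   `attr(, "zero_denominator")` counts zero-denominator events per ratio.
#' @export
derive_quantities <- function(panel, defs = attr(panel, "pending_defs")) {
  require_stage(panel, "raw", "derive_quantities")
  if (is.null(defs) || nrow(defs) == 0) {
    panel$stage <- "derived"
    return(panel)
  }
  raw_names <- panel$defs$name[panel$defs$kind == "raw"]
  vals <- panel$values
  newcols <- matrix(NA_real_, nrow(vals), nrow(defs),
    dimnames = list(rownames(vals), defs$name))
  zero_den <- stats::setNames(integer(nrow(defs)), defs$name)
  for (i in seq_len(nrow(defs))) {
    num <- split_components(defs$numerator[i])[[1]]
    den <- split_components(defs$denominator[i])[[1]]
    unknown <- setdiff(c(num, den), raw_names)
    if (length(unknown) > 0) {
      stop("definition '", defs$name[i], "' references unknown raw name(s): ",
        paste(unknown, collapse = ", "))
    }
    if (defs$kind[i] == "ratio") {
      if (length(num) == 0 || length(den) == 0) {
        stop("ratio '", defs$name[i], "' needs nonempty numerator and denominator")
      }
      nsum <- rowSums(vals[, num, drop = FALSE])
      dsum <- rowSums(vals[, den, drop = FALSE])
      out <- nsum / dsum
      z <- !is.na(dsum) & dsum == 0
      out[z] <- NA
      zero_den[i] <- sum(z)
      newcols[, i] <- out
    } else if (defs$kind[i] == "sum") {
      if (length(num) < 2 || length(den) > 0) {
        stop("sum '", defs$name[i], "' needs >= 2 numerator terms and no denominator")
      }
      newcols[, i] <- rowSums(vals[, num, drop = FALSE])
    } else {
      stop("derive_quantities handles only ratio and sum definitions")
    }
  }
  values <- cbind(vals, newcols)
  below <- cbind(panel$below_lod,
    matrix(FALSE, nrow(vals), nrow(defs), dimnames = dimnames(newcols)))
  defs_all <- rbind(panel$defs,
    data.frame(name = defs$name, kind = defs$kind, numerator = defs$numerator,
      denominator = defs$denominator,
      lod = if (!is.null(defs$lod)) defs$lod else NA_real_))
  out <- metabolite_panel(values, defs_all, below_lod = below, stage = "derived")
  attr(out, "zero_denominator") <- zero_den
  out
}

#' Dichotomize poorly detected quantities
#'
#' Columns with strictly more than `frac_threshold` of their readings
#' below the detection limit become below/above indicators (0 = below,
#' 1 = above); exactly 20% stays quantitative (the rule reads "more than
#' 20 percent"). Other columns are untouched.
#'
#' @param panel a derived-stage [metabolite_panel()] with below-LOD flags.
#' @param frac_threshold strict dichotomization threshold (default 0.20).
#' @return the panel at stage "dichotomized".
#' @export
dichotomize_by_lod <- function(panel, frac_threshold = 0.20) {
  require_stage(panel, c("raw", "derived"), "dichotomize_by_lod")
  if (panel$stage == "raw") panel <- derive_quantities(panel, defs = NULL)
  frac <- colMeans(panel$below_lod)
  flip <- which(frac > frac_threshold)
  for (j in flip) {
    panel$values[, j] <- as.numeric(!panel$below_lod[, j])
    panel$defs$kind[j] <- "dichotomized"
  }
  panel$stage <- "dichotomized"
  panel
}

#' Inverse-hyperbolic-sine transform
#'
#' Applies `x -> ln(x + sqrt(x^2 + 1))` elementwise to every quantitative
#' column (dichotomized columns are skipped). Close to a log transform for
#' large values, defined at zero, and monotone.
#'
#' @param panel a dichotomized-stage [metabolite_panel()] on the raw scale.
#' @return the panel at stage "transformed".
#' @export
arsinh_transform <- function(panel) {
  require_stage(panel, "dichotomized", "arsinh_transform")
  quant <- panel$defs$kind != "dichotomized"
  v <- panel$values[, quant, drop = FALSE]
  if (any(v < 0, na.rm = TRUE)) {
    stop("negative raw concentration encountered; concentrations must be nonnegative")
  }
  panel$values[, quant] <- asinh(v)
  panel$stage <- "transformed"
  panel
}

#' Mask outliers outside mean +/- k SD
#'
#' Per column, the mean and SD are computed once on the non-missing values
#' (no iterative re-estimation) and values outside `mean +/- k * SD` are
#' set missing. Dichotomized and zero-variance columns are left untouched
#' (with a warning for the latter).
#'
#' @param panel a transformed-stage [metabolite_panel()].
#' @param k interval half-width in SD units (default 5).
#' @return the panel at stage "masked"; `attr(, "n_masked")` counts masked
#'   values per column.
#' @export
mask_outliers <- function(panel, k = 5) {
  require_stage(panel, "transformed", "mask_outliers")
  n_masked <- stats::setNames(integer(ncol(panel$values)), colnames(panel$values))
  for (j in which(panel$defs$kind != "dichotomized")) {
    v <- panel$values[, j]
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      warning("column '", colnames(panel$values)[j],
        "' has zero SD; no outlier masking applied")
      next
    }
    out <- !is.na(v) & (v < mu - k * sdv | v > mu + k * sdv)
    panel$values[out, j] <- NA
    n_masked[j] <- sum(out)
  }
  panel$stage <- "masked"
  attr(panel, "n_masked") <- n_masked
  panel
}

#' Run the full metabolite preprocessing chain
#'
#' derive -> dichotomize -> arsinh -> outlier mask, with the study
#' defaults (strict 20% rule, 5-SD interval).
#'
#' @param panel a raw-stage [metabolite_panel()].
#' @param defs derived-quantity definitions (default: pending definitions).
#' @param frac_threshold dichotomization threshold.
#' @param k outlier interval half-width.
#' @return a masked-stage panel ready for association analysis.
#' @export
prepare_metabolites <- function(panel, defs = attr(panel, "pending_defs"),
                                frac_threshold = 0.20, k = 5) {
  panel <- derive_quantities(panel, defs)
  panel <- dichotomize_by_lod(panel, frac_threshold)
  panel <- arsinh_transform(panel)
  mask_outliers(panel, k)
}
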