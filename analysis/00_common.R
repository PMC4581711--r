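# Shared setup for the numbered analysis drivers: the study seed, the
# analysis configuration, deterministic reconstruction of the simulated
# cohorts, and small read/write helpers. Every driver can be run on its
# own; stages that need upstream results read them from results/.

library(triqtl)

STUDY_SEED <- as.integer(Sys.getenv("TRIQTL_SEED", "1"))
RESULTS <- "results"

study_config <- function() sim_config(seed = STUDY_SEED)

analysis_config <- function() default_config(seed = STUDY_SEED)

# The synthetic study is fully determined by the seed, so any driver can
# rebuild it instead of deserializing intermediate objects.
get_study <- function() simulate_study(study_config())

res_path <- function(...) {
  p <- file.path(RESULTS, ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

save_table <- function(df, ...) {
  p <- res_path(...)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA")
  message("  wrote ", p, " (", nrow(df), " rows)")
  invisible(p)
}

load_table <- function(...) {
  p <- file.path(RESULTS, ...)
  if (!file.exists(p)) {
    stop(p, " not found - run the earlier drivers first", call. = FALSE)
  }
  utils::read.delim(p, stringsAsFactors = FALSE)
}

# Preprocessing used by every downstream stage (fast; permutation-heavy
# stages cache their own outputs as TSVs instead).
get_prepared <- function(study = get_study()) {
  cfg <- analysis_config()
  list(
    study = study, cfg = cfg,
    M_d = prepare_metabolites(study$discovery$metabolites),
    M_r = prepare_metabolites(study$replication$metabolites),
    E_d = prepare_expression(study$discovery$expression,
      covariates = subset_covariates(study$discovery$covariates, c("age", "sex")),
      cfg = cfg))
}
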