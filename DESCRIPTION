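Package: triqtl
Title: Integrative SNP-Expression-Metabolite Association and Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking SNP gene doses, blood gene
    expression and targeted metabolite panels: genome-wide mQTL scanning with
    permutation-based false discovery rate control, LD-pruned lead-SNP
    selection and direction-consistent replication through proxy SNPs,
    cis/trans eQTL mapping with layer-specific Benjamini-Hochberg thresholds,
    expression-metabolite association, association-triangle discovery with a
    permutation/Poisson null, an adapted Mendelian randomization estimator on
    SNP-residualized metabolites, and a jackknife beta-attenuation mediation
    test. Includes a synthetic multi-omics cohort generator with planted
    direct, cis/trans-regulatory and expression-mediated effects so that every
    stage can be exercised against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    limma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
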