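Package: progwas
Title: Longitudinal Blood-Pressure Progression GWAS with Hot-Deck Phenotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide association studies of the
    progression of systolic blood pressure over repeated examinations.
    Provides a synthetic longitudinal cohort generator with configurable
    dropout mechanisms and planted genetic effects, regression-based
    diagnostics of the missing-data mechanism (MCAR versus MAR),
    correlation-weighted nearest-completer (hot-deck) imputation of
    longitudinal phenotypes, genotype quality control (identity-by-state
    relatedness screening, call-rate, Hardy-Weinberg and allele-frequency
    filters), single-marker and exhaustive two-marker allelic-interaction
    scans of the annual blood-pressure slope, genomic-control inflation
    estimation, and Monte-Carlo permutation validation of top findings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'association.R'
    'cohort-config.R'
    'imputation.R'
    'interaction.R'
    'io.R'
    'missingness.R'
    'permutation.R'
    'pipeline.R'
    'qc.R'
    'simulate-phenotypes.R'
    'simulate-genotypes.R'
    'utils.R'
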