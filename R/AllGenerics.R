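#' @import methods
NULL

#' Access the per-individual phenotype table
#'
#' @param x a [LongitudinalCohort-class] (or an object containing one).
#' @return A `data.frame` with one row per individual and columns
#'   `ID`, `SEX`, `BIRTH_YEAR`, then `AGE0..AGE3`, `SBP0..SBP3`,
#'   `MED0..MED3`, `SMK0..SMK3` (`NA` marks a missing measurement).
#' @export
setGeneric("phenoTable", function(x) standardGeneric("phenoTable"))

#' Number of individuals in a cohort or genotype object
#' @param x a cohort or genotype object.
#' @return integer count.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Individual identifiers
#' @param x a cohort or genotype object.
#' @return character vector of IDs.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' Additive dosage matrix (SNPs x individuals)
#' @param x a [GenotypeData-class].
#' @return numeric matrix with entries 0/1/2 (minor-allele count) or `NA`.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' SNP map (chromosome, position, alleles) with per-SNP annotations
#' @param x a [GenotypeData-class].
#' @return `data.frame` with columns `snp`, `chrom`, `pos`, `alleles`.
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' SNP identifiers
#' @param x a [GenotypeData-class].
#' @return character vector.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Completer indicator
#'
#' An individual is a completer when all four examinations were attended and
#' every AGE/SBP/MED/SMK measurement was recorded.
#'
#' @param x a [LongitudinalCohort-class].
#' @return logical vector, one element per individual.
#' @export
setGeneric("isCompleter", function(x) standardGeneric("isCompleter"))

#' Complete (pre-dropout) phenotypes of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return a [LongitudinalCohort-class].
#' @export
setGeneric("completePhenotypes", function(x) standardGeneric("completePhenotypes"))

#' Observed (post-dropout) phenotypes of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return a [LongitudinalCohort-class].
#' @export
setGeneric("observedPhenotypes", function(x) standardGeneric("observedPhenotypes"))

#' Genotypes of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return a [GenotypeData-class].
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Ground-truth record of a synthetic cohort
#'
#' @param x a [SyntheticCohort-class].
#' @return a list holding the generating configuration, realized latent
#'   slopes, true (unmasked) dosages, planted effects and injected relative
#'   pairs.
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' Completed phenotypes from an imputation run
#' @param x an [ImputationResult-class].
#' @return a [LongitudinalCohort-class] with no missing values.
#' @export
setGeneric("imputedPhenotypes", function(x) standardGeneric("imputedPhenotypes"))

#' Imputation audit table
#'
#' @param x an [ImputationResult-class].
#' @return `data.frame` with one row per non-completer: donor id, distance,
#'   and the comma-separated list of imputed slots.
#' @export
setGeneric("imputationAudit", function(x) standardGeneric("imputationAudit"))
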