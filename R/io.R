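#' @include AllClasses.R
NULL

#' Read and write phenotype tables
#'
#' Phenotypes travel as tab-delimited text with a header line, one row per
#' individual, columns `ID, SEX, BIRTH_YEAR, AGE0..AGE3, SBP0..SBP3,
#' MED0..MED3, SMK0..SMK3` and the literal token `NA` for missing values.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @param file path of the delimited text file.
#' @return `readPhenotypes()` returns a [LongitudinalCohort-class];
#'   `writePhenotypes()` returns `file` invisibly.
#' @export
writePhenotypes <- function(cohort, file) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  utils::write.table(phenoTable(cohort), file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(file) {
  ph <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c(ID = "character"), na.strings = "NA")
  LongitudinalCohort(ph)
}

#' Read and write genotype matrices
#'
#' Genotypes travel as additive dosage text in a PLINK-`.raw`-like layout:
#' a header line `ID` followed by the SNP identifiers, then one row per
#' individual with dosages 0/1/2 or `NA`.  The companion map file is
#' tab-delimited with columns `chrom, snp, pos, alleles`.
#'
#' @param geno a [GenotypeData-class].
#' @param file dosage file path.
#' @param mapFile map file path.
#' @return `readGenotypes()` returns a [GenotypeData-class];
#'   `writeGenotypes()` returns `file` invisibly.
#' @export
writeGenotypes <- function(geno, file, mapFile) {
  stopifnot(is(geno, "GenotypeData"))
  d <- t(dosageMatrix(geno))
  out <- data.frame(ID = rownames(d), d, check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  map <- snpMap(geno)
  utils::write.table(map[, c("chrom", "snp", "pos", "alleles")], mapFile,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(file, mapFile) {
  raw <- utils::read.table(file, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           colClasses = c(ID = "character"), na.strings = "NA")
  dosage <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(dosage) <- raw$ID
  map <- utils::read.table(mapFile, header = TRUE, sep = "\t",
                           colClasses = c(snp = "character"))
  stopifnot(identical(map$snp, rownames(dosage)))
  GenotypeData(dosage, map[, c("chrom", "pos", "alleles")])
}
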