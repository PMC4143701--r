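#' @include AllGenerics.R
NULL

## column layout shared by the whole package: four examination waves,
## four per-wave variables, plus invariant identifiers
.EXAMS <- 0:3
.WAVE_VARS <- c("AGE", "SBP", "MED", "SMK")
.ID_COLS <- c("ID", "SEX", "BIRTH_YEAR")

.waveCols <- function(vars = .WAVE_VARS) {
  as.vector(t(outer(vars, .EXAMS, paste0)))
}

.phenoCols <- function() c(.ID_COLS, .waveCols())

# ---------------------------------------------------------------------------
# LongitudinalCohort
# ---------------------------------------------------------------------------

#' Longitudinal blood-pressure cohort
#'
#' Wide per-individual phenotype table for a four-wave longitudinal study:
#' age, systolic blood pressure (mm Hg), antihypertensive medication (0/1)
#' and smoking status (0/1) at examinations 0--3, plus sex and birth year.
#' Missing measurements are `NA`; birth year and sex are always present.
#'
#' @slot pheno `data.frame`, one row per individual, columns
#'   `ID, SEX, BIRTH_YEAR, AGE0..AGE3, SBP0..SBP3, MED0..MED3, SMK0..SMK3`.
#' @export
setClass("LongitudinalCohort", representation(pheno = "data.frame"))

setValidity("LongitudinalCohort", function(object) {
  ph <- object@pheno
  miss <- setdiff(.phenoCols(), names(ph))
  if (length(miss) > 0)
    return(paste("missing phenotype columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(ph$ID))
    return("duplicated individual IDs")
  if (anyNA(ph$BIRTH_YEAR) || anyNA(ph$SEX))
    return("BIRTH_YEAR and SEX must never be missing")
  if (!all(ph$SEX %in% c(0, 1)))
    return("SEX must be coded 0/1")
  for (v in c("MED", "SMK")) {
    vals <- unlist(ph[paste0(v, .EXAMS)], use.names = FALSE)
    if (!all(vals %in% c(0, 1) | is.na(vals)))
      return(paste(v, "values must be 0/1 where present"))
  }
  sbp <- unlist(ph[paste0("SBP", .EXAMS)], use.names = FALSE)
  if (any(sbp <= 0, na.rm = TRUE))
    return("SBP must be positive where present")
  ages <- as.matrix(ph[paste0("AGE", .EXAMS)])
  for (i in seq_len(nrow(ages))) {
    a <- ages[i, !is.na(ages[i, ])]
    if (length(a) > 1 && any(diff(a) <= 0))
      return(sprintf("ages of individual %s not strictly increasing", ph$ID[i]))
  }
  TRUE
})

#' Construct a LongitudinalCohort from a phenotype table
#'
#' @param pheno `data.frame` in the wide per-individual layout (see
#'   [LongitudinalCohort-class]).
#' @return a validated `LongitudinalCohort`.
#' @export
LongitudinalCohort <- function(pheno) {
  pheno <- as.data.frame(pheno)
  pheno$ID <- as.character(pheno$ID)
  rownames(pheno) <- NULL
  new("LongitudinalCohort", pheno = pheno[, .phenoCols(), drop = FALSE])
}

#' @describeIn LongitudinalCohort phenotype table accessor
#' @param x a `LongitudinalCohort`.
#' @export
setMethod("phenoTable", "LongitudinalCohort", function(x) x@pheno)

#' @describeIn LongitudinalCohort number of individuals
#' @export
setMethod("nIndividuals", "LongitudinalCohort", function(x) nrow(x@pheno))

#' @describeIn LongitudinalCohort individual identifiers
#' @export
setMethod("individualIds", "LongitudinalCohort", function(x) x@pheno$ID)

#' @describeIn LongitudinalCohort completer indicator (all 16 wave values present)
#' @export
setMethod("isCompleter", "LongitudinalCohort", function(x) {
  rowSums(is.na(x@pheno[, .waveCols(), drop = FALSE])) == 0L
})

setMethod("show", "LongitudinalCohort", function(object) {
  n <- nIndividuals(object)
  nc <- sum(isCompleter(object))
  cat(sprintf("LongitudinalCohort: %d individuals (%d completers, %d non-completers)\n",
              n, nc, n - nc))
  pm <- colMeans(is.na(object@pheno[, paste0("SBP", .EXAMS)]))
  cat(sprintf("  SBP missing by exam: %s\n",
              paste(sprintf("%.0f%%", 100 * pm), collapse = " / ")))
})

# ---------------------------------------------------------------------------
# GenotypeData
# ---------------------------------------------------------------------------

#' Additive genotype container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding an
#' additive dosage matrix (minor-allele counts 0/1/2, `NA` = not called)
#' with SNPs as rows and individuals as columns.  `rowData` carries the SNP
#' map: chromosome, 1-based position and the allele pair.
#'
#' @export
#' @import SummarizedExperiment
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!all(d %in% c(0, 1, 2) | is.na(d)))
    return("dosages must be 0, 1, 2 or NA")
  need <- setdiff(c("chrom", "pos", "alleles"),
                  colnames(SummarizedExperiment::rowData(object)))
  if (length(need) > 0)
    return(paste("rowData lacks:", paste(need, collapse = ", ")))
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("SNP and individual names are required as dimnames")
  TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of minor-allele counts, SNPs as rows and
#'   individuals as columns, with dimnames set.
#' @param map `data.frame` with columns `chrom`, `pos`, `alleles` (and
#'   optionally `snp`, which must then match `rownames(dosage)`).
#' @return a validated [GenotypeData-class].
#' @export
GenotypeData <- function(dosage, map) {
  map <- as.data.frame(map)
  if ("snp" %in% names(map)) {
    stopifnot(identical(as.character(map$snp), rownames(dosage)))
    map$snp <- NULL
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(map))
  new("GenotypeData", se)
}

#' @describeIn GenotypeData dosage matrix accessor (SNPs x individuals)
#' @param x a `GenotypeData`.
#' @export
setMethod("dosageMatrix", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypeData SNP map accessor
#' @export
setMethod("snpMap", "GenotypeData", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cbind(snp = rownames(x), rd)
})

#' @describeIn GenotypeData SNP identifiers
#' @export
setMethod("snpIds", "GenotypeData", function(x) rownames(x))

#' @describeIn GenotypeData individual identifiers
#' @export
setMethod("individualIds", "GenotypeData", function(x) colnames(x))

#' @describeIn GenotypeData number of individuals
#' @export
setMethod("nIndividuals", "GenotypeData", function(x) ncol(x))

setMethod("show", "GenotypeData", function(object) {
  d <- dosageMatrix(object)
  cat(sprintf("GenotypeData: %d SNPs x %d individuals (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
})

# ---------------------------------------------------------------------------
# CohortConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' Created by [cohortConfig()]; see that constructor for the meaning and
#' default of every field.  `params` holds the documented generator
#' constants (blood-pressure model coefficients, noise scales, behaviour
#' probabilities).
#'
#' @export
setClass("CohortConfig", representation(
  nIndividuals = "integer",
  nSnps = "integer",
  examYears = "numeric",
  mafRange = "numeric",
  genoMissingRate = "numeric",
  dropoutMode = "character",
  dropoutStrength = "numeric",
  baseAttendance = "numeric",
  maskBaselineExam = "logical",
  plantedMain = "data.frame",
  plantedInteractions = "data.frame",
  nRelativePairs = "integer",
  copyErrorRate = "numeric",
  seed = "integer",
  params = "list"
))

setValidity("CohortConfig", function(object) {
  if (object@nIndividuals < 2L)
    return("nIndividuals must be at least 2")
  if (length(object@examYears) != 4L || any(diff(object@examYears) <= 0))
    return("examYears must be 4 strictly increasing calendar years")
  if (length(object@mafRange) != 2L || object@mafRange[1] > object@mafRange[2] ||
      object@mafRange[1] <= 0 || object@mafRange[2] > 0.5)
    return("mafRange must be an interval within (0, 0.5]")
  if (!object@dropoutMode %in% c("none", "mcar", "mar_age", "mnar_sbp"))
    return("unknown dropoutMode")
  if (object@genoMissingRate < 0 || object@genoMissingRate > 1)
    return("genoMissingRate must lie in [0,1]")
  if (object@copyErrorRate < 0 || object@copyErrorRate > 1)
    return("copyErrorRate must lie in [0,1]")
  pm <- object@plantedMain
  if (nrow(pm) > 0 && any(pm$snp < 1 | pm$snp > object@nSnps))
    return("planted main-effect SNP index out of range")
  pi <- object@plantedInteractions
  if (nrow(pi) > 0 && any(c(pi$snp1, pi$snp2) < 1 | c(pi$snp1, pi$snp2) > object@nSnps))
    return("planted interaction SNP index out of range")
  if (2L * object@nRelativePairs > object@nIndividuals)
    return("nRelativePairs too large for the sample size")
  TRUE
})

# ---------------------------------------------------------------------------
# SyntheticCohort
# ---------------------------------------------------------------------------

#' Synthetic cohort with known ground truth
#'
#' Bundles the complete (pre-dropout) phenotypes, the observed phenotypes
#' after missingness masking, the genotype matrix, and a `truth` list with
#' everything needed to score downstream stages against the generator:
#' the configuration, realized latent slopes, true dosages, planted effects
#' and injected relative pairs.
#'
#' @slot complete,observed [LongitudinalCohort-class] objects.
#' @slot genotypes a [GenotypeData-class].
#' @slot truth a list.
#' @export
setClass("SyntheticCohort", representation(
  complete = "LongitudinalCohort",
  observed = "LongitudinalCohort",
  genotypes = "GenotypeData",
  truth = "list"
))

setValidity("SyntheticCohort", function(object) {
  pc <- phenoTable(object@complete)
  po <- phenoTable(object@observed)
  if (!identical(dim(pc), dim(po)) || !identical(pc$ID, po$ID))
    return("complete and observed phenotypes must describe the same individuals")
  wc <- as.matrix(pc[, .waveCols()])
  wo <- as.matrix(po[, .waveCols()])
  obs <- !is.na(wo)
  if (!isTRUE(all.equal(wc[obs], wo[obs])))
    return("observed values must equal the complete values where present")
  TRUE
})

#' @describeIn SyntheticCohort complete phenotypes
#' @param x a `SyntheticCohort`.
#' @export
setMethod("completePhenotypes", "SyntheticCohort", function(x) x@complete)

#' @describeIn SyntheticCohort observed (masked) phenotypes
#' @export
setMethod("observedPhenotypes", "SyntheticCohort", function(x) x@observed)

#' @describeIn SyntheticCohort genotype data
#' @export
setMethod("genotypes", "SyntheticCohort", function(x) x@genotypes)

#' @describeIn SyntheticCohort ground-truth list
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @describeIn SyntheticCohort number of individuals
#' @export
setMethod("nIndividuals", "SyntheticCohort", function(x) nIndividuals(x@complete))

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort\n")
  show(object@observed)
  show(object@genotypes)
  cat(sprintf("  dropout mode: %s; planted effects: %d main, %d interaction; relative pairs: %d\n",
              object@truth$config@dropoutMode,
              nrow(object@truth$config@plantedMain),
              nrow(object@truth$config@plantedInteractions),
              object@truth$config@nRelativePairs))
})

# ---------------------------------------------------------------------------
# Imputation machinery
# ---------------------------------------------------------------------------

#' Correlation-derived distance weights for hot-deck imputation
#'
#' Pearson correlations, over completers, of the blood-pressure change
#' `SBP3 - SBP0` with baseline age (`alpha1`), baseline medication
#' (`alpha2`), baseline smoking (`alpha3`) and baseline SBP (`beta`).
#' The distance weights are the absolute ratios `|alpha_k / beta|`; the
#' SBP term itself carries implicit weight 1.
#'
#' @export
setClass("ImputationWeights", representation(
  alpha1 = "numeric", alpha2 = "numeric", alpha3 = "numeric",
  beta = "numeric",
  wAge = "numeric", wMed = "numeric", wSmk = "numeric"
))

setValidity("ImputationWeights", function(object) {
  r <- c(object@alpha1, object@alpha2, object@alpha3, object@beta)
  if (any(abs(r) > 1 + 1e-12))
    return("correlations must lie in [-1, 1]")
  w <- c(object@wAge, object@wMed, object@wSmk)
  if (any(!is.finite(w)) || any(w < 0))
    return("weights must be finite and non-negative")
  TRUE
})

setMethod("show", "ImputationWeights", function(object) {
  cat(sprintf(paste0("ImputationWeights: alpha = (%.3f, %.3f, %.3f), beta = %.3f\n",
                     "  weights (age, med, smk) = (%.3f, %.3f, %.3f); SBP weight = 1\n"),
              object@alpha1, object@alpha2, object@alpha3, object@beta,
              object@wAge, object@wMed, object@wSmk))
})

#' Per-variable per-exam normalization constants
#'
#' Means and standard deviations of AGE/SBP/MED/SMK at each exam, computed
#' over all individuals with the value observed at that exam.  The SD is the
#' population form `sqrt(mean(x^2) - mean(x)^2)`.  A zero SD marks the term
#' as unusable; the distance drops it with weight 0.
#'
#' @slot mu,sigma numeric 4x4 matrices (variables x exams).
#' @export
setClass("NormalizationConstants", representation(
  mu = "matrix", sigma = "matrix"
))

setValidity("NormalizationConstants", function(object) {
  if (!identical(dim(object@mu), c(4L, 4L)) ||
      !identical(dim(object@sigma), c(4L, 4L)))
    return("mu and sigma must be 4x4 (variables x exams)")
  if (any(object@sigma < 0, na.rm = TRUE))
    return("sigma must be non-negative")
  TRUE
})

setMethod("show", "NormalizationConstants", function(object) {
  cat("NormalizationConstants (mu | sigma):\n")
  for (v in rownames(object@mu))
    cat(sprintf("  %s: %s | %s\n", v,
                paste(sprintf("%.2f", object@mu[v, ]), collapse = " "),
                paste(sprintf("%.2f", object@sigma[v, ]), collapse = " ")))
})

#' Result of a cohort imputation run
#'
#' @slot cohort the completed [LongitudinalCohort-class].
#' @slot audit `data.frame` with one row per non-completer: `id`, `donor`,
#'   distance `d`, tie flag, and the imputed slots.
#' @slot weights the [ImputationWeights-class] used.
#' @slot constants the [NormalizationConstants-class] used.
#' @slot examYears average calendar years of the four exams.
#' @export
setClass("ImputationResult", representation(
  cohort = "LongitudinalCohort",
  audit = "data.frame",
  weights = "ImputationWeights",
  constants = "NormalizationConstants",
  examYears = "numeric"
))

#' @describeIn ImputationResult completed phenotypes
#' @param x an `ImputationResult`.
#' @export
setMethod("imputedPhenotypes", "ImputationResult", function(x) x@cohort)

#' @describeIn ImputationResult audit table
#' @export
setMethod("imputationAudit", "ImputationResult", function(x) x@audit)

setMethod("show", "ImputationResult", function(object) {
  cat(sprintf("ImputationResult: %d individuals, %d imputed non-completers\n",
              nIndividuals(object@cohort), nrow(object@audit)))
  cat(sprintf("  exam years: %s\n", paste(object@examYears, collapse = ", ")))
  show(object@weights)
})

# ---------------------------------------------------------------------------
# Reports
# ---------------------------------------------------------------------------

#' Missing-data mechanism report
#'
#' Output of [mcarJointTest()]: baseline SBP regressed on the follow-up
#' presence indicators, with and without baseline-age adjustment, and the
#' joint F-test of all presence coefficients.
#'
#' @slot pUnadjusted,pAdjusted joint p-values (NA when undefined).
#' @slot unadjustedFit,adjustedFit coefficient tables.
#' @slot verdict `"consistent-with-MCAR"`, `"MAR-suspected"` or
#'   `"not-explained-by-age"`.
#' @slot droppedIndicators presence indicators dropped for zero variance.
#' @slot nUsed number of individuals entering the fits.
#' @export
setClass("MechanismReport", representation(
  pUnadjusted = "numeric", pAdjusted = "numeric",
  unadjustedFit = "data.frame", adjustedFit = "data.frame",
  verdict = "character", droppedIndicators = "character",
  nUsed = "integer"
))

setValidity("MechanismReport", function(object) {
  p <- c(object@pUnadjusted, object@pAdjusted)
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p-values must lie in [0,1]")
  TRUE
})

setMethod("show", "MechanismReport", function(object) {
  cat("MechanismReport\n")
  cat(sprintf("  joint p (unadjusted):   %s\n", format(object@pUnadjusted, digits = 3)))
  cat(sprintf("  joint p (age-adjusted): %s\n", format(object@pAdjusted, digits = 3)))
  cat(sprintf("  verdict: %s (n = %d)\n", object@verdict, object@nUsed))
  if (length(object@droppedIndicators) > 0)
    cat(sprintf("  dropped indicators: %s\n",
                paste(object@droppedIndicators, collapse = ", ")))
})

#' Genotype quality-control report
#'
#' @slot ibsMean,ibsSd mean and SD of the pairwise IBS values.
#' @slot flaggedPairs `data.frame` of related pairs (`id1`, `id2`, `ibs`).
#' @slot samplesRemoved `data.frame` (`id`, `reason`).
#' @slot snpsRemoved `data.frame` (`snp`, `reason`).
#' @slot snpInfo per-SNP `data.frame` (`snp`, `chrom`, `pos`, `alleles`,
#'   `callRate`, `maf`, `hweP`) on the retained samples.
#' @slot nSamplesKept,nSnpsKept surviving counts.
#' @export
setClass("QcReport", representation(
  ibsMean = "numeric", ibsSd = "numeric",
  flaggedPairs = "data.frame",
  samplesRemoved = "data.frame",
  snpsRemoved = "data.frame",
  snpInfo = "data.frame",
  nSamplesKept = "integer", nSnpsKept = "integer"
))

setValidity("QcReport", function(object) {
  ok <- c("relatedness", "sample_missingness", "snp_callrate", "hwe", "maf")
  bad <- setdiff(c(object@samplesRemoved$reason, object@snpsRemoved$reason), ok)
  if (length(bad) > 0)
    return(paste("unknown removal reason:", paste(unique(bad), collapse = ", ")))
  TRUE
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport\n")
  cat(sprintf("  IBS mean %.4f, SD %.4f; %d related pair(s) flagged\n",
              object@ibsMean, object@ibsSd, nrow(object@flaggedPairs)))
  cat(sprintf("  samples removed: %d; SNPs removed: %d\n",
              nrow(object@samplesRemoved), nrow(object@snpsRemoved)))
  cat(sprintf("  kept: %d samples, %d SNPs\n",
              object@nSamplesKept, object@nSnpsKept))
})

#' Monte-Carlo permutation result
#'
#' @slot id SNP (or pair) label.
#' @slot statObserved observed test statistic.
#' @slot k replicates with a strictly larger statistic.
#' @slot nReplicates number of permutation replicates.
#' @slot pMc the plain estimator `k / N`.
#' @slot pMcConservative the positively-biased estimator `(k + 1) / (N + 1)`.
#' @slot nTies replicates whose statistic tied the observed one (not counted
#'   in `k`).
#' @slot seed base seed of the replicate stream.
#' @export
setClass("PermutationResult", representation(
  id = "character", statObserved = "numeric",
  k = "numeric", nReplicates = "numeric",
  pMc = "numeric", pMcConservative = "numeric",
  nTies = "numeric", seed = "integer"
))

setValidity("PermutationResult", function(object) {
  if (object@k < 0 || object@k > object@nReplicates)
    return("k must lie in [0, nReplicates]")
  if (object@pMc < 0 || object@pMc > 1) return("pMc must lie in [0,1]")
  TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult [%s]: stat = %.4g, k = %d of N = %d\n",
              object@id, object@statObserved, object@k, object@nReplicates))
  cat(sprintf("  p_MC = %.3g, (k+1)/(N+1) = %.3g, ties = %d\n",
              object@pMc, object@pMcConservative, object@nTies))
})
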