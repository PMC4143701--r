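#' @include AllClasses.R
NULL

#' Generator constants of the synthetic cohort
#'
#' One place for every numeric constant of the phenotype generator, so
#' simulation studies are reproducible from the configuration alone.
#' Values can be overridden through the `params` argument of
#' [cohortConfig()].
#'
#' \describe{
#'   \item{age0Range}{baseline age drawn uniformly on this integer range
#'     (years); default `c(20, 70)`.}
#'   \item{pMale}{probability of SEX = 1; default 0.5.}
#'   \item{sbpIntercept}{systolic blood pressure (mm Hg) of a baseline-age-0
#'     female before individual effects; default 95.}
#'   \item{sbpAgeCoef}{cross-sectional mm Hg per year of baseline age;
#'     default 0.5.}
#'   \item{sbpSexCoef}{mm Hg added for males; default 5.}
#'   \item{sbpIndivSD}{SD of the person-level SBP intercept (mm Hg),
#'     the source of within-person tracking; default 10.}
#'   \item{sbpNoiseSD}{SD of the per-exam measurement noise (mm Hg);
#'     default 8.}
#'   \item{slopeMean}{mean latent SBP progression (mm Hg/year); default 0.5.}
#'   \item{slopeSD}{SD of the latent progression; default 0.4.}
#'   \item{slopeAgeCoef}{progression change per year of baseline age away
#'     from `ageCenter` (mm Hg/year per year); default 0.01, making the
#'     trait positively correlated with baseline age.}
#'   \item{ageCenter, sbpCenter}{centering constants for the dropout logits
#'     (years, mm Hg); defaults 45 and 130.}
#'   \item{medThreshold, medScale}{medication uptake follows
#'     `plogis((SBP - medThreshold)/medScale)` per exam and is persistent
#'     once started; defaults 140 and 10.}
#'   \item{smkPrev}{baseline smoking prevalence; default 0.3.}
#'   \item{smkPersist}{wave-to-wave probability of keeping the previous
#'     smoking status; default 0.95.}
#'   \item{examYearJitterSD}{SD of the integer jitter of each individual's
#'     actual exam calendar year around the cohort schedule (years),
#'     clamped to \eqn{\pm 2}; default 0.8.}
#'   \item{roundSbp}{round SBP to whole mm Hg (field convention);
#'     default `TRUE`.}
#' }
#'
#' @return named list of defaults.
#' @export
generatorDefaults <- function() {
  list(
    age0Range = c(20L, 70L),
    pMale = 0.5,
    sbpIntercept = 95,
    sbpAgeCoef = 0.5,
    sbpSexCoef = 5,
    sbpIndivSD = 10,
    sbpNoiseSD = 8,
    slopeMean = 0.5,
    slopeSD = 0.4,
    slopeAgeCoef = 0.01,
    ageCenter = 45,
    sbpCenter = 130,
    medThreshold = 140,
    medScale = 10,
    smkPrev = 0.3,
    smkPersist = 0.95,
    examYearJitterSD = 0.8,
    roundSbp = TRUE
  )
}

#' Configure the synthetic cohort generator
#'
#' Defines the study conditions emulated by [simulateCohort()]: a four-wave
#' longitudinal blood-pressure study with roughly five-year exam spacing,
#' age-dependent (or blood-pressure-dependent) dropout, and independent
#' biallelic SNPs with optional planted main and interaction effects on the
#' annual SBP slope and optional injected cryptic-relative pairs.
#'
#' @param nIndividuals number of individuals (at least 2).
#' @param nSnps number of SNPs.
#' @param examYears four strictly increasing calendar years of the cohort
#'   exam schedule; default `c(1993, 1998, 2003, 2009)`.
#' @param mafRange interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly; default `c(0.05, 0.5)`.
#' @param genoMissingRate per-entry genotype missingness probability.
#' @param dropoutMode `"none"`, `"mcar"`, `"mar_age"` (attendance logit
#'   decreasing in baseline age) or `"mnar_sbp"` (decreasing in the
#'   current, possibly unobserved, SBP).
#' @param dropoutStrength logistic slope per unit of the mode's predictor
#'   (per year of age, per mm Hg); positive values make attendance fall
#'   with the predictor.
#' @param baseAttendance attendance probability of follow-up waves at the
#'   predictor's centering value; default 0.75, which yields roughly half
#'   non-completers over waves 1--3.
#' @param maskBaselineExam also subject exam 0 to dropout (default `FALSE`,
#'   matching designs where baseline measurement is a condition of entry).
#' @param plantedMain `data.frame` with columns `snp` (index) and `effect`
#'   (mm Hg/year added to the latent slope per minor allele).
#' @param plantedInteractions `data.frame` with columns `snp1`, `snp2`,
#'   `effect` (mm Hg/year per unit of the dosage product).
#' @param nRelativePairs number of cryptic-relative pairs to inject by
#'   near-copying genotype vectors.
#' @param copyErrorRate per-SNP probability that the copied member of a
#'   relative pair is re-drawn from the population instead.
#' @param seed integer seed; all generator components draw from named
#'   sub-streams of this seed.
#' @param params overrides for [generatorDefaults()].
#' @return a validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nIndividuals = 50, nSnps = 10, seed = 1)
#' cohort <- simulateCohort(cfg)
#' @export
cohortConfig <- function(nIndividuals,
                         nSnps,
                         examYears = c(1993, 1998, 2003, 2009),
                         mafRange = c(0.05, 0.5),
                         genoMissingRate = 0,
                         dropoutMode = c("none", "mcar", "mar_age", "mnar_sbp"),
                         dropoutStrength = 0.1,
                         baseAttendance = 0.75,
                         maskBaselineExam = FALSE,
                         plantedMain = data.frame(snp = integer(), effect = numeric()),
                         plantedInteractions = data.frame(snp1 = integer(),
                                                          snp2 = integer(),
                                                          effect = numeric()),
                         nRelativePairs = 0L,
                         copyErrorRate = 0,
                         seed = 1L,
                         params = list()) {
  dropoutMode <- match.arg(dropoutMode)
  p <- generatorDefaults()
  unknown <- setdiff(names(params), names(p))
  .stopIf(length(unknown) > 0, "unknown generator parameter(s): %s",
          paste(unknown, collapse = ", "))
  p[names(params)] <- params
  new("CohortConfig",
      nIndividuals = as.integer(nIndividuals),
      nSnps = as.integer(nSnps),
      examYears = as.numeric(examYears),
      mafRange = as.numeric(mafRange),
      genoMissingRate = as.numeric(genoMissingRate),
      dropoutMode = dropoutMode,
      dropoutStrength = as.numeric(dropoutStrength),
      baseAttendance = as.numeric(baseAttendance),
      maskBaselineExam = isTRUE(maskBaselineExam),
      plantedMain = as.data.frame(plantedMain),
      plantedInteractions = as.data.frame(plantedInteractions),
      nRelativePairs = as.integer(nRelativePairs),
      copyErrorRate = as.numeric(copyErrorRate),
      seed = as.integer(seed),
      params = p)
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d individuals, %d SNPs, exams %s\n",
              object@nIndividuals, object@nSnps,
              paste(object@examYears, collapse = "/")))
  cat(sprintf("  dropout: %s (strength %.3g, base attendance %.2f); MAF in [%.2f, %.2f]\n",
              object@dropoutMode, object@dropoutStrength, object@baseAttendance,
              object@mafRange[1], object@mafRange[2]))
})
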