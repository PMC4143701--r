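#' @include cohort-config.R
NULL

## Draw every latent quantity of the phenotype generator from the
## "phenotypes" stream.  Materialization is kept separate so planted genetic
## effects can modify the latent slope and re-materialize the very same
## noise realization.
.drawPhenotypeLatents <- function(config) {
  set.seed(.streamSeed(config@seed, "phenotypes"))
  n <- config@nIndividuals
  p <- config@params
  age0 <- sample(p$age0Range[1]:p$age0Range[2], n, replace = TRUE)
  birth <- .roundHalfUp(config@examYears[1]) - age0
  sex <- stats::rbinom(n, 1, p$pMale)
  jitter <- matrix(pmin(2, pmax(-2, .roundHalfUp(
    stats::rnorm(n * 4, 0, p$examYearJitterSD)))), n, 4)
  examYearMat <- matrix(.roundHalfUp(config@examYears), n, 4, byrow = TRUE) + jitter
  ageMat <- examYearMat - birth
  slope <- p$slopeMean + p$slopeAgeCoef * (age0 - p$ageCenter) +
    stats::rnorm(n, 0, p$slopeSD)
  list(
    ids = sprintf("IND%05d", seq_len(n)),
    age0 = age0, birth = birth, sex = sex,
    examYearMat = examYearMat, ageMat = ageMat,
    slope = slope,
    b = stats::rnorm(n, 0, p$sbpIndivSD),
    eps = matrix(stats::rnorm(n * 4, 0, p$sbpNoiseSD), n, 4),
    uMed = matrix(stats::runif(n * 4), n, 4),
    uSmk = matrix(stats::runif(n * 4), n, 4)
  )
}

## Deterministic map from latents (plus a possibly effect-adjusted slope)
## to the complete phenotype table.
.materializePhenotypes <- function(latents, config, slope = latents$slope) {
  p <- config@params
  n <- length(latents$ids)
  sbp <- matrix(NA_real_, n, 4)
  med <- matrix(NA_real_, n, 4)
  smk <- matrix(NA_real_, n, 4)
  base <- p$sbpIntercept + p$sbpAgeCoef * latents$age0 +
    p$sbpSexCoef * latents$sex + latents$b
  for (k in 1:4) {
    sbp[, k] <- base + slope * (latents$ageMat[, k] - latents$ageMat[, 1]) +
      latents$eps[, k]
    if (p$roundSbp) sbp[, k] <- .roundHalfUp(sbp[, k])
    pMed <- stats::plogis((sbp[, k] - p$medThreshold) / p$medScale)
    started <- as.numeric(latents$uMed[, k] < pMed)
    med[, k] <- if (k == 1) started else pmax(med[, k - 1], started)
    if (k == 1) {
      smk[, k] <- as.numeric(latents$uSmk[, k] < p$smkPrev)
    } else {
      keep <- latents$uSmk[, k] < p$smkPersist
      smk[, k] <- ifelse(keep, smk[, k - 1], 1 - smk[, k - 1])
    }
  }
  ph <- data.frame(ID = latents$ids, SEX = latents$sex,
                   BIRTH_YEAR = latents$birth)
  for (k in 1:4) ph[[paste0("AGE", k - 1)]] <- latents$ageMat[, k]
  for (k in 1:4) ph[[paste0("SBP", k - 1)]] <- sbp[, k]
  for (k in 1:4) ph[[paste0("MED", k - 1)]] <- med[, k]
  for (k in 1:4) ph[[paste0("SMK", k - 1)]] <- smk[, k]
  LongitudinalCohort(ph)
}

#' Generate complete longitudinal phenotypes
#'
#' Simulates birth year, sex and four-wave AGE/SBP/MED/SMK trajectories
#' under the model documented in [generatorDefaults()]: SBP rises linearly
#' with an individual latent slope around an age- and sex-dependent
#' baseline with person-level tracking, medication uptake is a persistent
#' logistic function of current SBP, and smoking is a highly persistent
#' binary state.  No values are missing; apply [applyDropout()] (or use
#' [simulateCohort()]) for missingness.
#'
#' @param config a [CohortConfig-class].
#' @return a complete [LongitudinalCohort-class].
#' @export
generatePhenotypes <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  .materializePhenotypes(.drawPhenotypeLatents(config), config)
}
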