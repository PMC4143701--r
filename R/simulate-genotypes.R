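#' @include simulate-phenotypes.R
NULL

#' Generate an independent-locus genotype matrix
#'
#' Per SNP a minor allele frequency is drawn uniformly from the configured
#' range and dosages are i.i.d. Binomial(2, MAF) across individuals (no
#' linkage disequilibrium).  Entry-level missingness is applied at
#' `genoMissingRate`.  The true (unmasked) dosage matrix and true MAFs are
#' kept in the object metadata so downstream stages can be scored against
#' the generator.
#'
#' @param config a [CohortConfig-class].
#' @return a [GenotypeData-class]; `S4Vectors::metadata()` holds `maf` and
#'   `trueDosage`.
#' @export
generateGenotypes <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  set.seed(.streamSeed(config@seed, "genotypes"))
  n <- config@nIndividuals
  m <- config@nSnps
  maf <- stats::runif(m, config@mafRange[1], config@mafRange[2])
  dosage <- matrix(stats::rbinom(m * n, 2L, rep(maf, times = n)), m, n)
  chrom <- rep(seq(1L, 21L, by = 2L), length.out = m)
  pos <- integer(m)
  for (ch in unique(chrom)) pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 5000L
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
  rownames(dosage) <- sprintf("snp%05d", seq_len(m))
  colnames(dosage) <- sprintf("IND%05d", seq_len(n))
  observed <- dosage
  if (config@genoMissingRate > 0)
    observed[matrix(stats::runif(m * n) < config@genoMissingRate, m, n)] <- NA
  geno <- GenotypeData(observed,
                       data.frame(chrom = chrom, pos = pos,
                                  alleles = paste(a1, a2, sep = "/")))
  S4Vectors::metadata(geno)$maf <- maf
  S4Vectors::metadata(geno)$trueDosage <- dosage
  geno
}

#' Inject cryptic-relative pairs into a genotype matrix
#'
#' For each pair, the second member's genotype vector becomes a copy of the
#' first member's with each dosage independently re-drawn from the
#' population (Binomial(2, MAF)) with probability `copyErrorRate`.
#' `copyErrorRate = 0` yields an exact duplicate (IBS 1); `1` yields an
#' unrelated individual.
#'
#' @param geno a [GenotypeData-class].
#' @param nPairs number of pairs; members are sampled without replacement.
#' @param copyErrorRate per-entry resampling probability in \[0, 1\].
#' @param seed integer seed for the "relatives" stream.
#' @return the modified [GenotypeData-class];
#'   `S4Vectors::metadata()$relativePairs` records the pairs.
#' @export
injectRelatives <- function(geno, nPairs, copyErrorRate = 0, seed = 1L) {
  stopifnot(is(geno, "GenotypeData"))
  .stopIf(copyErrorRate < 0 || copyErrorRate > 1,
          "copyErrorRate must lie in [0, 1]")
  n <- ncol(geno)
  .stopIf(2L * nPairs > n, "need 2 * nPairs <= number of individuals")
  if (nPairs == 0L) return(geno)
  set.seed(.streamSeed(seed, "relatives"))
  members <- sample.int(n, 2L * nPairs)
  id1 <- members[seq(1L, by = 2L, length.out = nPairs)]
  id2 <- members[seq(2L, by = 2L, length.out = nPairs)]
  dos <- dosageMatrix(geno)
  true <- S4Vectors::metadata(geno)$trueDosage
  if (is.null(true)) true <- dos
  maf <- S4Vectors::metadata(geno)$maf
  if (is.null(maf)) maf <- rowMeans(dos, na.rm = TRUE) / 2
  m <- nrow(dos)
  for (k in seq_len(nPairs)) {
    v <- true[, id1[k]]
    redraw <- stats::runif(m) < copyErrorRate
    v[redraw] <- stats::rbinom(sum(redraw), 2L, maf[redraw])
    true[, id2[k]] <- v
    ## the copied member keeps their own missingness pattern
    dos[, id2[k]] <- ifelse(is.na(dos[, id2[k]]), NA, v)
  }
  out <- GenotypeData(dos, snpMap(geno)[, c("chrom", "pos", "alleles")])
  S4Vectors::metadata(out) <- S4Vectors::metadata(geno)
  S4Vectors::metadata(out)$trueDosage <- true
  S4Vectors::metadata(out)$relativePairs <-
    data.frame(id1 = colnames(dos)[id1], id2 = colnames(dos)[id2])
  out
}

#' Plant genetic effects on the blood-pressure slope
#'
#' Each planted main effect adds `effect * dosage` (mm Hg/year per minor
#' allele) to the individual's latent SBP slope; each planted interaction
#' adds `effect * dosage1 * dosage2`.  Phenotypes are re-materialized from
#' the same latent noise, so a zero effect leaves them bit-identical.
#' Effects use the true (unmasked) dosages.  Planting on a zero-variance
#' SNP is recorded as a warning in the truth list.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param config the [CohortConfig-class] whose `plantedMain` /
#'   `plantedInteractions` tables define the effects.
#' @return the updated [SyntheticCohort-class].
#' @export
plantEffects <- function(cohort, config) {
  stopifnot(is(cohort, "SyntheticCohort"))
  truth <- cohort@truth
  dos <- truth$trueDosage
  slope <- truth$latents$slope
  warnings <- character()
  pm <- config@plantedMain
  for (r in seq_len(nrow(pm))) {
    d <- dos[pm$snp[r], ]
    if (stats::var(d) == 0) {
      warnings <- c(warnings,
                    sprintf("planted main effect on zero-variance SNP %d", pm$snp[r]))
      warning(warnings[length(warnings)], call. = FALSE)
    }
    slope <- slope + pm$effect[r] * d
  }
  pint <- config@plantedInteractions
  for (r in seq_len(nrow(pint))) {
    prod <- dos[pint$snp1[r], ] * dos[pint$snp2[r], ]
    if (stats::var(prod) == 0) {
      warnings <- c(warnings,
                    sprintf("planted interaction on zero-variance pair (%d, %d)",
                            pint$snp1[r], pint$snp2[r]))
      warning(warnings[length(warnings)], call. = FALSE)
    }
    slope <- slope + pint$effect[r] * prod
  }
  complete <- .materializePhenotypes(truth$latents, config, slope = slope)
  truth$effectiveSlope <- slope
  truth$plantWarnings <- warnings
  observed <- .applyMask(complete, .missingMask(cohort@observed))
  new("SyntheticCohort", complete = complete, observed = observed,
      genotypes = cohort@genotypes, truth = truth)
}

.missingMask <- function(cohort) is.na(as.matrix(phenoTable(cohort)[, .waveCols()]))

.applyMask <- function(cohort, mask) {
  ph <- phenoTable(cohort)
  w <- as.matrix(ph[, .waveCols()])
  w[mask] <- NA
  ph[, .waveCols()] <- w
  LongitudinalCohort(ph)
}

#' Apply a dropout mechanism to a synthetic cohort
#'
#' Attendance of each follow-up wave (exams 1--3; exam 0 too when
#' `maskBaselineExam`) is Bernoulli with
#' `logit(p) = qlogis(baseAttendance) - dropoutStrength * (predictor - center)`,
#' where the predictor is baseline age (`mar_age`), the current complete
#' SBP (`mnar_sbp`), or constant (`mcar`).  A missed wave masks AGE, SBP,
#' MED and SMK together; birth year and sex are never masked, and patterns
#' are non-monotone (individuals may return).  Masking always starts from
#' the complete phenotypes, so re-application is idempotent.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param config the [CohortConfig-class]; its `dropoutMode`,
#'   `dropoutStrength`, `baseAttendance`, `maskBaselineExam` and `seed`
#'   drive the mechanism.
#' @return the updated [SyntheticCohort-class]; `cohortTruth()$attendance`
#'   holds the realized attendance matrix.
#' @export
applyDropout <- function(cohort, config) {
  stopifnot(is(cohort, "SyntheticCohort"))
  truth <- cohort@truth
  n <- nIndividuals(cohort)
  attend <- matrix(TRUE, n, 4)
  if (config@dropoutMode != "none") {
    set.seed(.streamSeed(config@seed, "dropout"))
    p <- config@params
    waves <- if (config@maskBaselineExam) 1:4 else 2:4
    sbp <- as.matrix(phenoTable(cohort@complete)[, paste0("SBP", .EXAMS)])
    age0 <- phenoTable(cohort@complete)$AGE0
    for (k in waves) {
      pred <- switch(config@dropoutMode,
                     mcar = rep(0, n),
                     mar_age = age0 - p$ageCenter,
                     mnar_sbp = sbp[, k] - p$sbpCenter)
      pa <- stats::plogis(stats::qlogis(config@baseAttendance) -
                            config@dropoutStrength * pred)
      if (any(pa <= 0 | pa >= 1)) {
        warning("attendance probability clamped to (0, 1)", call. = FALSE)
        pa <- pmin(1 - 1e-12, pmax(1e-12, pa))
      }
      attend[, k] <- stats::runif(n) < pa
    }
  }
  mask <- matrix(FALSE, n, length(.waveCols()))
  colnames(mask) <- .waveCols()
  for (k in 1:4)
    mask[, paste0(.WAVE_VARS, k - 1)] <- !attend[, k]
  truth$attendance <- attend
  observed <- .applyMask(cohort@complete, mask)
  new("SyntheticCohort", complete = cohort@complete, observed = observed,
      genotypes = cohort@genotypes, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Runs the generator end to end: complete phenotypes, genotypes,
#' cryptic-relative injection, planted genetic effects, then dropout
#' masking.  Each component draws from its own named sub-stream of
#' `config@seed`, so identical seeds give bit-identical cohorts and
#' toggling one component leaves the others' draws unchanged.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' cohort <- simulateCohort(cohortConfig(nIndividuals = 100, nSnps = 20,
#'                                       dropoutMode = "mar_age", seed = 7))
#' table(isCompleter(observedPhenotypes(cohort)))
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  latents <- .drawPhenotypeLatents(config)
  complete <- .materializePhenotypes(latents, config)
  geno <- generateGenotypes(config)
  if (config@nRelativePairs > 0L)
    geno <- injectRelatives(geno, config@nRelativePairs,
                            config@copyErrorRate, seed = config@seed)
  truth <- list(config = config, latents = latents,
                trueDosage = S4Vectors::metadata(geno)$trueDosage,
                maf = S4Vectors::metadata(geno)$maf,
                relativePairs = S4Vectors::metadata(geno)$relativePairs,
                effectiveSlope = latents$slope)
  cohort <- new("SyntheticCohort", complete = complete, observed = complete,
                genotypes = geno, truth = truth)
  if (nrow(config@plantedMain) > 0 || nrow(config@plantedInteractions) > 0)
    cohort <- plantEffects(cohort, config)
  applyDropout(cohort, config)
}
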