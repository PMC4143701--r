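#' @include AllClasses.R
NULL

#' Split a cohort into completers and non-completers
#'
#' A completer attended all four examinations with every AGE/SBP/MED/SMK
#' value recorded; completers serve as imputation donors.  The partition is
#' exhaustive and disjoint.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @return list with elements `completers` and `noncompleters`
#'   (both [LongitudinalCohort-class], possibly empty the latter) and the
#'   logical index `isCompleter`.
#' @export
extractCompleters <- function(cohort) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  cc <- isCompleter(cohort)
  .stopIf(!any(cc), "no completers: imputation is impossible")
  ph <- phenoTable(cohort)
  list(completers = LongitudinalCohort(ph[cc, , drop = FALSE]),
       noncompleters = LongitudinalCohort(ph[!cc, , drop = FALSE]),
       isCompleter = cc)
}

#' Average calendar years of the four examinations
#'
#' Every attended exam contributes its calendar year, recovered as
#' `BIRTH_YEAR + AGE_i`; the exam's calendar year is the mean over
#' attendees, rounded to the nearest whole year.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @return numeric vector of 4 calendar years.
#' @export
averageExamYears <- function(cohort) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  ph <- phenoTable(cohort)
  vapply(.EXAMS, function(i) {
    yr <- ph$BIRTH_YEAR + ph[[paste0("AGE", i)]]
    .stopIf(all(is.na(yr)), "exam %d attended by nobody", i)
    .roundHalfUp(mean(yr, na.rm = TRUE))
  }, numeric(1))
}

#' Impute missing ages from birth year
#'
#' Fills every missing `AGE_i` with `examYear_i - BIRTH_YEAR`; present ages
#' are untouched.  After this step age is complete for everyone, so the
#' age terms of the donor distance are always active.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @param examYears the 4 average exam calendar years
#'   (default [averageExamYears()] of `cohort`).
#' @return the completed-age [LongitudinalCohort-class].
#' @export
imputeAges <- function(cohort, examYears = averageExamYears(cohort)) {
  stopifnot(is(cohort, "LongitudinalCohort"), length(examYears) == 4L)
  ph <- phenoTable(cohort)
  for (i in .EXAMS) {
    col <- paste0("AGE", i)
    fill <- is.na(ph[[col]])
    ph[[col]][fill] <- examYears[i + 1L] - ph$BIRTH_YEAR[fill]
  }
  .stopIf(any(unlist(ph[paste0("AGE", .EXAMS)]) <= 0),
          "imputed age not positive; check exam years and birth years")
  LongitudinalCohort(ph)
}

#' Correlation-derived imputation weights
#'
#' Over completers, with `dSBP = SBP3 - SBP0`: `alpha1 = cor(dSBP, AGE0)`,
#' `alpha2 = cor(dSBP, MED0)`, `alpha3 = cor(dSBP, SMK0)` and
#' `beta = cor(dSBP, SBP0)`.  The donor-distance weights are the absolute
#' ratios `|alpha_k / beta|`; a zero-variance predictor gets correlation 0
#' (with a warning) and hence weight 0, while `|beta|` below `1e-8` is a
#' hard error because every weight would be undefined.
#'
#' @param completers a [LongitudinalCohort-class] of completers (at least 3).
#' @return an [ImputationWeights-class].
#' @export
computeWeights <- function(completers) {
  stopifnot(is(completers, "LongitudinalCohort"))
  .stopIf(nIndividuals(completers) < 3L, "need at least 3 completers")
  .stopIf(!all(isCompleter(completers)), "non-completers in the donor set")
  ph <- phenoTable(completers)
  dsbp <- ph$SBP3 - ph$SBP0
  corOrZero <- function(x, label) {
    if (stats::var(x) == 0 || stats::var(dsbp) == 0) {
      warning(sprintf("%s has zero variance over completers; correlation set to 0",
                      label), call. = FALSE)
      return(0)
    }
    stats::cor(dsbp, x)
  }
  a1 <- corOrZero(ph$AGE0, "AGE0")
  a2 <- corOrZero(ph$MED0, "MED0")
  a3 <- corOrZero(ph$SMK0, "SMK0")
  beta <- if (stats::var(ph$SBP0) == 0 || stats::var(dsbp) == 0) 0
          else stats::cor(dsbp, ph$SBP0)
  .stopIf(abs(beta) < 1e-8,
          "correlation of SBP change with baseline SBP is ~0; weights undefined")
  new("ImputationWeights", alpha1 = a1, alpha2 = a2, alpha3 = a3, beta = beta,
      wAge = abs(a1 / beta), wMed = abs(a2 / beta), wSmk = abs(a3 / beta))
}

#' Per-variable per-exam normalization constants
#'
#' Mean and population SD (`sqrt(mean(x^2) - mean(x)^2)`) of each of
#' AGE/SBP/MED/SMK at each exam, over all individuals with the value
#' observed there.  One set of constants normalizes completers and
#' non-completers alike, so donor distances compare values on a single
#' scale.
#'
#' @param cohort a [LongitudinalCohort-class] (typically the full cohort
#'   after age imputation).
#' @return a [NormalizationConstants-class].
#' @export
normalizationConstants <- function(cohort) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  ph <- phenoTable(cohort)
  mu <- sigma <- matrix(NA_real_, 4, 4,
                        dimnames = list(.WAVE_VARS, paste0("exam", .EXAMS)))
  for (v in .WAVE_VARS) for (i in .EXAMS) {
    x <- ph[[paste0(v, i)]]
    x <- x[!is.na(x)]
    if (length(x) == 0) next
    m <- mean(x)
    mu[v, i + 1L] <- m
    sigma[v, i + 1L] <- sqrt(max(0, mean(x^2) - m^2))
  }
  new("NormalizationConstants", mu = mu, sigma = sigma)
}

## Normalized 16-column wave matrix (AGE0..3, SBP0..3, MED0..3, SMK0..3).
## Zero-sigma or unavailable terms normalize to 0; the distance drops them
## through a zero column weight.
.normalizedWaves <- function(ph, constants) {
  out <- matrix(0, nrow(ph), 16L, dimnames = list(NULL, .waveCols()))
  for (v in .WAVE_VARS) for (i in .EXAMS) {
    col <- paste0(v, i)
    s <- constants@sigma[v, i + 1L]
    if (is.na(s) || s == 0) next
    z <- (ph[[col]] - constants@mu[v, i + 1L]) / s
    z[is.na(z)] <- 0          # missing slots are gated by the indicator
    out[, col] <- z
  }
  out
}

## Per-column distance weights; terms with zero/undefined sigma are dropped
## (weight 0) with a warning when their variable weight was positive.
.columnWeights <- function(weights, constants) {
  w <- c(AGE = weights@wAge, SBP = 1, MED = weights@wMed, SMK = weights@wSmk)
  out <- numeric(16L)
  names(out) <- .waveCols()
  for (v in .WAVE_VARS) for (i in .EXAMS) {
    s <- constants@sigma[v, i + 1L]
    col <- paste0(v, i)
    if (is.na(s) || s == 0) {
      if (w[[v]] > 0)
        warning(sprintf("zero SD for %s; its distance term is dropped", col),
                call. = FALSE)
      out[col] <- 0
    } else {
      out[col] <- w[[v]]
    }
  }
  out
}

#' Correlation-weighted donor distance
#'
#' Distance between a non-completer `N` and completer donors `C`:
#' the sum over exams of squared differences of normalized values,
#' with the SBP term carrying weight 1, the age term `|alpha1/beta|`,
#' medication `|alpha2/beta|` and smoking `|alpha3/beta|`.  Only the
#' non-completer's presence gates a term (donors have everything); ages
#' are assumed complete (run [imputeAges()] first), so age terms are
#' always active.
#'
#' @param noncompleter one-row phenotype `data.frame` (or a
#'   [LongitudinalCohort-class] with one individual).
#' @param completers a [LongitudinalCohort-class] of donors.
#' @param weights an [ImputationWeights-class].
#' @param constants a [NormalizationConstants-class].
#' @return numeric vector of distances, named by donor ID.
#' @export
imputationDistance <- function(noncompleter, completers, weights, constants) {
  if (is(noncompleter, "LongitudinalCohort")) noncompleter <- phenoTable(noncompleter)
  stopifnot(nrow(noncompleter) == 1L, is(completers, "LongitudinalCohort"))
  .stopIf(anyNA(noncompleter[paste0("AGE", .EXAMS)]),
          "ages must be imputed before computing donor distances")
  phC <- phenoTable(completers)
  zN <- .normalizedWaves(noncompleter, constants)
  zC <- .normalizedWaves(phC, constants)
  .stopIf(!all(is.finite(zN)) || !all(is.finite(zC)),
          "non-finite normalized value in distance computation")
  present <- as.numeric(!is.na(as.matrix(noncompleter[, .waveCols()])))
  colw <- .columnWeights(weights, constants) * present
  d <- as.vector((zC - matrix(zN, nrow(phC), 16L, byrow = TRUE))^2 %*% colw)
  names(d) <- phC$ID
  d
}

#' Deterministic donor selection from candidate distances
#'
#' Returns the donor with minimal distance; exact ties are broken by the
#' lexicographically smallest donor ID, and all tied donors are reported.
#'
#' @param d numeric vector of candidate distances.
#' @param ids donor IDs (default `names(d)`).
#' @return list with `donor`, `d`, and `tied` (IDs sharing the minimum).
#' @export
selectDonor <- function(d, ids = names(d)) {
  stopifnot(length(d) >= 1L, length(ids) == length(d))
  dmin <- min(d)
  tied <- sort(ids[d == dmin])
  list(donor = tied[1L], d = dmin, tied = tied)
}

#' Nearest completer for a non-completer
#'
#' @inheritParams imputationDistance
#' @return list with `donor` (ID), `d` (distance) and `tied` (IDs at the
#'   minimal distance).
#' @export
nearestCompleter <- function(noncompleter, completers, weights, constants) {
  selectDonor(imputationDistance(noncompleter, completers, weights, constants))
}

#' Transfer missing values from the closest donor
#'
#' Fills every missing SBP/MED/SMK slot of the non-completer with the
#' donor's value at the same exam; observed slots are never overwritten and
#' ages are not transferred (they come from [imputeAges()]).
#'
#' @param noncompleter one-row phenotype `data.frame`.
#' @param donor one-row complete phenotype `data.frame`.
#' @return list with the completed row (`record`) and the character vector
#'   of imputed slot names (`slots`).
#' @export
transferValues <- function(noncompleter, donor) {
  stopifnot(nrow(noncompleter) == 1L, nrow(donor) == 1L)
  slots <- .waveCols(c("SBP", "MED", "SMK"))
  .stopIf(anyNA(donor[slots]), "donor is missing a needed slot")
  filled <- character()
  for (col in slots) {
    if (is.na(noncompleter[[col]])) {
      noncompleter[[col]] <- donor[[col]]
      filled <- c(filled, col)
    }
  }
  list(record = noncompleter, slots = filled)
}

#' Hot-deck imputation of a longitudinal cohort
#'
#' Runs the full six-step nearest-completer procedure: (1) average exam
#' calendar years, (2) age completion from birth year, (3) correlation
#' weights over completers, (4) normalized donor distances, (5) nearest
#' donor per non-completer, (6) value transfer.  The output phenotypes have
#' no missing values; the audit table records, per non-completer, the
#' donor, the distance, whether the minimum was tied, and the imputed
#' slots.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @param sameSexDonors restrict donors to completers of the same sex
#'   (default `FALSE`; the distance itself has no sex term).
#' @return an [ImputationResult-class].
#' @examples
#' cohort <- observedPhenotypes(simulateCohort(
#'   cohortConfig(nIndividuals = 120, nSnps = 2,
#'                dropoutMode = "mar_age", seed = 3)))
#' res <- imputeCohort(cohort)
#' head(imputationAudit(res))
#' @export
imputeCohort <- function(cohort, sameSexDonors = FALSE) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  examYears <- averageExamYears(cohort)
  aged <- imputeAges(cohort, examYears)
  parts <- extractCompleters(aged)
  weights <- computeWeights(parts$completers)
  constants <- normalizationConstants(aged)

  ph <- phenoTable(aged)
  phC <- phenoTable(parts$completers)
  audit <- data.frame(id = character(), donor = character(), d = numeric(),
                      tie = logical(), imputedSlots = character(),
                      stringsAsFactors = FALSE)
  ncIdx <- which(!parts$isCompleter)
  for (j in ncIdx) {
    row <- ph[j, , drop = FALSE]
    donors <- parts$completers
    if (sameSexDonors) {
      same <- phC$SEX == row$SEX
      .stopIf(!any(same), "no same-sex donor for individual %s", row$ID)
      donors <- LongitudinalCohort(phC[same, , drop = FALSE])
    }
    sel <- nearestCompleter(row, donors, weights, constants)
    tr <- transferValues(row, phenoTable(donors)[individualIds(donors) == sel$donor, ,
                                                 drop = FALSE])
    ph[j, ] <- tr$record
    audit <- rbind(audit, data.frame(
      id = row$ID, donor = sel$donor, d = sel$d,
      tie = length(sel$tied) > 1L,
      imputedSlots = paste(tr$slots, collapse = ","),
      stringsAsFactors = FALSE))
  }
  new("ImputationResult",
      cohort = LongitudinalCohort(ph), audit = audit,
      weights = weights, constants = constants, examYears = examYears)
}
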