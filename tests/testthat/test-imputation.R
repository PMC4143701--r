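maskedCohort <- function(n = 120, seed = 5, strength = 0.1) {
  simulateCohort(cohortConfig(nIndividuals = n, nSnps = 2,
                              dropoutMode = "mar_age",
                              dropoutStrength = strength, seed = seed))
}

test_that("completer extraction partitions the cohort exhaustively", {
  co <- maskedCohort()
  obs <- observedPhenotypes(co)
  parts <- extractCompleters(obs)
  expect_equal(nIndividuals(parts$completers) + nIndividuals(parts$noncompleters),
               nIndividuals(obs))
  expect_true(all(isCompleter(parts$completers)))
  expect_false(any(isCompleter(parts$noncompleters)))

  ph <- handPheno(5)
  ph$SMK2[2] <- NA                      # one missing value suffices
  parts2 <- extractCompleters(LongitudinalCohort(ph))
  expect_equal(individualIds(parts2$noncompleters), "H002")

  noDrop <- observedPhenotypes(simulateCohort(
    cohortConfig(nIndividuals = 30, nSnps = 2, seed = 2)))
  expect_equal(nIndividuals(extractCompleters(noDrop)$noncompleters), 0)
})

test_that("average exam years are attended-year means, rounded", {
  ph <- handPheno(10)                   # unjittered: exact schedule
  expect_equal(averageExamYears(LongitudinalCohort(ph)),
               c(1993, 1998, 2003, 2009))

  ph2 <- handPheno(2)
  ph2$AGE0 <- c(30, 40)
  ph2$BIRTH_YEAR <- c(1962, 1954)       # exam-0 years 1992 and 1994
  ph2$AGE1 <- ph2$AGE0 + 5; ph2$AGE2 <- ph2$AGE0 + 10; ph2$AGE3 <- ph2$AGE0 + 16
  expect_equal(averageExamYears(LongitudinalCohort(ph2))[1], 1993)

  ## jittered generator cohort vs direct mean-and-round oracle
  co <- maskedCohort(seed = 9)
  obs <- phenoTable(observedPhenotypes(co))
  got <- averageExamYears(observedPhenotypes(co))
  for (i in 0:3) {
    yr <- obs$BIRTH_YEAR + obs[[paste0("AGE", i)]]
    expect_equal(got[i + 1], floor(mean(yr, na.rm = TRUE) + 0.5))
  }
})

test_that("age imputation fills from birth year and recovers unjittered truth", {
  ph <- handPheno(3)
  ph$BIRTH_YEAR[1] <- 1960
  ph[1, paste0("AGE", 0:3)] <- NA
  before <- ph$AGE1[2]
  aged <- phenoTable(imputeAges(LongitudinalCohort(ph),
                                examYears = c(1993, 1998, 2003, 2009)))
  expect_equal(unlist(aged[1, paste0("AGE", 0:3)], use.names = FALSE),
               c(33, 38, 43, 49))
  expect_equal(aged$AGE1[2], before)

  ## with jitter off, masked ages are recovered exactly
  co <- simulateCohort(cohortConfig(nIndividuals = 150, nSnps = 2,
                                    dropoutMode = "mar_age", seed = 11,
                                    params = list(examYearJitterSD = 0)))
  aged2 <- imputeAges(observedPhenotypes(co))
  expect_equal(as.matrix(phenoTable(aged2)[, paste0("AGE", 0:3)]),
               as.matrix(phenoTable(completePhenotypes(co))[, paste0("AGE", 0:3)]))
})

test_that("imputation weights are correlation ratios with documented edge rules", {
  ph <- handPheno(40)
  ph$SBP3 <- 3 * ph$SBP0                # dSBP = 2*SBP0 exactly
  w <- suppressWarnings(computeWeights(LongitudinalCohort(ph)))
  expect_equal(w@beta, 1.0, tolerance = 1e-12)

  ph2 <- handPheno(40, seed = 2)
  ph2$MED0 <- 0
  expect_warning(w2 <- computeWeights(LongitudinalCohort(ph2)), "MED0")
  expect_equal(w2@alpha2, 0)
  expect_equal(w2@wMed, 0)

  ## 5-row hand data vs direct correlation formula
  ph3 <- handPheno(5, seed = 3)
  ph3$MED0 <- c(0, 1, 0, 1, 1)
  ph3$SMK0 <- c(1, 0, 0, 1, 0)
  w3 <- computeWeights(LongitudinalCohort(ph3))
  dsbp <- ph3$SBP3 - ph3$SBP0
  corHand <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  }
  expect_equal(w3@alpha1, corHand(dsbp, ph3$AGE0), tolerance = 1e-12)
  expect_equal(w3@alpha2, corHand(dsbp, ph3$MED0), tolerance = 1e-12)
  expect_equal(w3@beta, corHand(dsbp, ph3$SBP0), tolerance = 1e-12)
  expect_equal(w3@wAge, abs(w3@alpha1 / w3@beta), tolerance = 1e-12)

  ph4 <- handPheno(40, seed = 4)
  ph4$SBP3 <- ph4$SBP0 + round(rnorm(40, 20, 5))  # dSBP independent of SBP0?
  ph4$SBP0 <- 120                       # zero variance -> beta undefined
  expect_error(suppressWarnings(computeWeights(LongitudinalCohort(ph4))),
               "weights undefined")
})

test_that("normalization uses shared population constants", {
  co <- maskedCohort(seed = 21)
  aged <- imputeAges(observedPhenotypes(co))
  const <- normalizationConstants(aged)
  ph <- phenoTable(aged)
  for (v in c("AGE", "SBP")) for (i in 0:3) {
    x <- ph[[paste0(v, i)]]
    x <- x[!is.na(x)]
    expect_equal(const@mu[v, i + 1], mean(x), tolerance = 1e-12)
    expect_equal(const@sigma[v, i + 1],
                 sqrt(mean(x^2) - mean(x)^2), tolerance = 1e-10)
  }
  ## normalized value of mu is 0; of mu + sigma is 1
  probe <- ph[1, , drop = FALSE]
  probe$SBP1 <- const@mu["SBP", 2]
  z <- progwas:::.normalizedWaves(probe, const)
  expect_equal(unname(z[1, "SBP1"]), 0)
  probe$SBP1 <- const@mu["SBP", 2] + const@sigma["SBP", 2]
  z <- progwas:::.normalizedWaves(probe, const)
  expect_equal(unname(z[1, "SBP1"]), 1)
})

test_that("donor distance matches the definition term by term", {
  co <- maskedCohort(n = 80, seed = 31)
  aged <- imputeAges(observedPhenotypes(co))
  parts <- extractCompleters(aged)
  W <- computeWeights(parts$completers)
  const <- normalizationConstants(aged)
  phN <- phenoTable(parts$noncompleters)
  phC <- phenoTable(parts$completers)

  ## identity: a completer row at distance 0 from itself
  self <- imputationDistance(phC[1, , drop = FALSE], parts$completers, W, const)
  expect_equal(unname(self[1]), 0)

  ## single-SBP-term arithmetic: only SBP0 observed, ages equal
  probe <- phC[1, , drop = FALSE]
  probe$ID <- "PROBE"
  probe[paste0("SBP", 1:3)] <- NA
  probe[paste0("MED", 0:3)] <- NA
  probe[paste0("SMK", 0:3)] <- NA
  probe$SBP0 <- phC$SBP0[1] + const@sigma["SBP", 1]   # one normalized unit
  d <- imputationDistance(probe, parts$completers, W, const)
  expect_equal(unname(d[1]), 1.0, tolerance = 1e-12)

  ## oracle equivalence on random non-completer/completer pairs
  for (r in 1:25) {
    i <- sample(nrow(phN), 1)
    dAll <- imputationDistance(phN[i, , drop = FALSE], parts$completers, W, const)
    j <- sample(nrow(phC), 1)
    expect_equal(unname(dAll[j]),
                 oracleDistance(phN[i, ], phC[j, ], W, const),
                 tolerance = 1e-12)
  }
})

test_that("nearest-donor search is an exact argmin with a deterministic tie rule", {
  co <- maskedCohort(n = 100, seed = 41)
  aged <- imputeAges(observedPhenotypes(co))
  parts <- extractCompleters(aged)
  W <- computeWeights(parts$completers)
  const <- normalizationConstants(aged)
  phN <- phenoTable(parts$noncompleters)
  for (i in seq_len(min(10, nrow(phN)))) {
    d <- imputationDistance(phN[i, , drop = FALSE], parts$completers, W, const)
    sel <- nearestCompleter(phN[i, , drop = FALSE], parts$completers, W, const)
    expect_equal(sel$d, min(d))
    expect_identical(sel$donor, names(d)[which.min(d)])
  }
  ## ties break to the lexicographically smallest ID, all ties reported
  sel <- selectDonor(c(B = 0.5, A = 0.5, C = 0.7))
  expect_identical(sel$donor, "A")
  expect_identical(sel$tied, c("A", "B"))
  ## single donor wins regardless of distance
  expect_identical(selectDonor(c(Z = 42))$donor, "Z")
})

test_that("value transfer fills only missing slots from the donor", {
  tr <- transferValues(table1Noncompleter(), table1Donor())
  expect_equal(tr$record$SBP0, 110)
  expect_equal(tr$record$SBP3, 149)
  expect_equal(tr$record$MED3, 1)
  expect_equal(tr$record$SMK0, 0)
  expect_equal(tr$record$SBP1, 125)     # observed value untouched
  expect_setequal(tr$slots, c("SBP0", "SBP3", "MED0", "MED3", "SMK0", "SMK3"))

  ## nothing missing among SBP/MED/SMK -> unchanged
  donor <- table1Donor()
  tr2 <- transferValues(donor, donor)
  expect_identical(tr2$record, donor)
  expect_length(tr2$slots, 0)

  bad <- table1Donor()
  bad$SBP2 <- NA
  expect_error(transferValues(table1Noncompleter(), bad), "donor is missing")
})

test_that("cohort imputation is idempotent, value-preserving and donor-consistent", {
  noDrop <- observedPhenotypes(simulateCohort(
    cohortConfig(nIndividuals = 60, nSnps = 2, seed = 51)))
  res0 <- imputeCohort(noDrop)
  expect_identical(phenoTable(imputedPhenotypes(res0)), phenoTable(noDrop))
  expect_equal(nrow(imputationAudit(res0)), 0)

  co <- maskedCohort(n = 150, seed = 51)
  obs <- observedPhenotypes(co)
  res <- imputeCohort(obs)
  out <- phenoTable(imputedPhenotypes(res))
  expect_false(anyNA(out))

  ## observed values never change
  phObs <- phenoTable(obs)
  w <- setdiff(names(phObs), c("ID", "SEX", "BIRTH_YEAR"))
  seen <- !is.na(phObs[, w])
  expect_equal(as.matrix(out[, w])[seen], as.matrix(phObs[, w])[seen])

  ## every imputed SBP/MED/SMK value equals its donor's slot value
  audit <- imputationAudit(res)
  for (r in seq_len(nrow(audit))) {
    slots <- strsplit(audit$imputedSlots[r], ",")[[1]]
    donorRow <- out[out$ID == audit$donor[r], ]
    impRow <- out[out$ID == audit$id[r], ]
    for (s in slots) expect_equal(impRow[[s]], donorRow[[s]])
  }

  ## re-imputing the completed table is the identity
  res2 <- imputeCohort(imputedPhenotypes(res))
  expect_identical(phenoTable(imputedPhenotypes(res2)), out)
})
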