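test_that("the generator is deterministic and its streams are independent", {
  cfg <- cohortConfig(nIndividuals = 80, nSnps = 30, dropoutMode = "mar_age",
                      seed = 42)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(phenoTable(observedPhenotypes(a)),
                   phenoTable(observedPhenotypes(b)))
  expect_identical(dosageMatrix(genotypes(a)), dosageMatrix(genotypes(b)))

  ## toggling relative injection must not shift phenotype or genotype draws
  cfgRel <- cohortConfig(nIndividuals = 80, nSnps = 30,
                         dropoutMode = "mar_age", nRelativePairs = 3,
                         copyErrorRate = 0.1, seed = 42)
  c <- simulateCohort(cfgRel)
  expect_identical(phenoTable(completePhenotypes(a)),
                   phenoTable(completePhenotypes(c)))
  pairs <- cohortTruth(c)$relativePairs
  untouched <- setdiff(colnames(dosageMatrix(genotypes(c))), pairs$id2)
  expect_identical(dosageMatrix(genotypes(a))[, untouched],
                   dosageMatrix(genotypes(c))[, untouched])
})

test_that("degenerate noise settings give constant SBP trajectories", {
  cfg <- cohortConfig(nIndividuals = 20, nSnps = 2, seed = 3,
                      params = list(sbpNoiseSD = 0, slopeMean = 0,
                                    slopeSD = 0, slopeAgeCoef = 0))
  ph <- phenoTable(generatePhenotypes(cfg))
  sbp <- as.matrix(ph[, paste0("SBP", 0:3)])
  expect_true(all(apply(sbp, 1, function(x) length(unique(x)) == 1)))
  expect_error(cohortConfig(nIndividuals = 1, nSnps = 2), "at least 2")
})

test_that("trait-age correlation matches a large-sample oracle of the same equations", {
  cfg <- cohortConfig(nIndividuals = 2000, nSnps = 2, seed = 7)
  ph <- phenoTable(generatePhenotypes(cfg))
  r <- cor((ph$SBP3 - ph$SBP0) / (ph$AGE3 - ph$AGE0), ph$AGE0)

  ## independent large-n simulation of the generative equations
  p <- generatorDefaults()
  set.seed(99)
  n <- 1e5
  age0 <- sample(20:70, n, replace = TRUE)
  slope <- p$slopeMean + p$slopeAgeCoef * (age0 - p$ageCenter) +
    rnorm(n, 0, p$slopeSD)
  dt <- 16
  dsbp <- slope * dt + rnorm(n, 0, p$sbpNoiseSD) - rnorm(n, 0, p$sbpNoiseSD)
  rOracle <- cor(dsbp / dt, age0)
  expect_gt(r, 0)                      # configured sign: positive
  expect_lt(abs(r - rOracle), 0.1)
})

test_that("genotype generation respects MAF, missingness and determinism", {
  cfg <- cohortConfig(nIndividuals = 10000, nSnps = 5,
                      mafRange = c(0.5, 0.5), seed = 5)
  g <- generateGenotypes(cfg)
  af <- rowMeans(dosageMatrix(g)) / 2
  expect_true(all(af > 0.49 & af < 0.51))
  expect_false(anyNA(dosageMatrix(g)))

  cfgM <- cohortConfig(nIndividuals = 500, nSnps = 40,
                       genoMissingRate = 0.1, seed = 5)
  gm <- generateGenotypes(cfgM)
  expect_gt(mean(is.na(dosageMatrix(gm))), 0.07)
  expect_lt(mean(is.na(dosageMatrix(gm))), 0.13)
  expect_identical(dosageMatrix(generateGenotypes(cfgM)), dosageMatrix(gm))
})

test_that("dropout masking preserves unmasked values and mechanism structure", {
  cfgNone <- cohortConfig(nIndividuals = 100, nSnps = 2,
                          dropoutMode = "none", seed = 8)
  co <- simulateCohort(cfgNone)
  expect_identical(phenoTable(observedPhenotypes(co)),
                   phenoTable(completePhenotypes(co)))

  cfg <- cohortConfig(nIndividuals = 1000, nSnps = 2,
                      dropoutMode = "mar_age", dropoutStrength = 0.1,
                      seed = 8)
  co <- simulateCohort(cfg)
  po <- phenoTable(observedPhenotypes(co))
  pc <- phenoTable(completePhenotypes(co))
  w <- setdiff(names(po), c("ID", "SEX", "BIRTH_YEAR"))
  obs <- !is.na(po[, w])
  expect_equal(as.matrix(po[, w])[obs], as.matrix(pc[, w])[obs])
  expect_false(anyNA(po$BIRTH_YEAR))
  expect_false(anyNA(po$SEX))
  expect_false(anyNA(po$SBP0))        # baseline exam not masked by default

  ## attendance falls with baseline age under mar_age
  attendance <- rowSums(!is.na(po[, paste0("SBP", 1:3)]))
  fit <- summary(lm(attendance ~ pc$AGE0))$coefficients
  expect_lt(fit[2, 1], 0)
  expect_lt(fit[2, 4], 0.01)
})

test_that("planted effects shift trajectories by exactly the configured amount", {
  base <- cohortConfig(nIndividuals = 150, nSnps = 5, seed = 21,
                       mafRange = c(0.3, 0.4),
                       params = list(sbpNoiseSD = 0, slopeSD = 0,
                                     slopeAgeCoef = 0, examYearJitterSD = 0,
                                     roundSbp = FALSE))
  noEffect <- cohortConfig(nIndividuals = 150, nSnps = 5, seed = 21,
                           mafRange = c(0.3, 0.4),
                           plantedMain = data.frame(snp = 1, effect = 0),
                           params = list(sbpNoiseSD = 0, slopeSD = 0,
                                         slopeAgeCoef = 0, examYearJitterSD = 0,
                                         roundSbp = FALSE))
  expect_identical(phenoTable(completePhenotypes(simulateCohort(base))),
                   phenoTable(completePhenotypes(simulateCohort(noEffect))))

  planted <- cohortConfig(nIndividuals = 150, nSnps = 5, seed = 21,
                          mafRange = c(0.3, 0.4),
                          plantedMain = data.frame(snp = 1, effect = 1.5),
                          params = list(sbpNoiseSD = 0, slopeSD = 0,
                                        slopeAgeCoef = 0, examYearJitterSD = 0,
                                        roundSbp = FALSE))
  co <- simulateCohort(planted)
  ph <- phenoTable(completePhenotypes(co))
  trait <- (ph$SBP3 - ph$SBP0) / (ph$AGE3 - ph$AGE0)
  dos <- cohortTruth(co)$trueDosage[1, ]
  means <- tapply(trait, dos, mean)
  expect_equal(as.numeric(diff(as.numeric(means))), c(1.5, 1.5),
               tolerance = 1e-12)
})

test_that("relative injection controls pair IBS from duplicate to background", {
  cfg <- cohortConfig(nIndividuals = 60, nSnps = 400, seed = 13)
  g <- generateGenotypes(cfg)
  gDup <- injectRelatives(g, nPairs = 2, copyErrorRate = 0, seed = 13)
  pairs <- S4Vectors::metadata(gDup)$relativePairs
  ibs <- ibsMatrix(gDup)
  for (r in seq_len(nrow(pairs)))
    expect_equal(ibs[pairs$id1[r], pairs$id2[r]], 1.0)

  gBg <- injectRelatives(g, nPairs = 2, copyErrorRate = 1, seed = 13)
  ibsBg <- ibsMatrix(gBg)
  off <- ibsBg[upper.tri(ibsBg)]
  pairIbs <- mapply(function(a, b) ibsBg[a, b],
                    S4Vectors::metadata(gBg)$relativePairs$id1,
                    S4Vectors::metadata(gBg)$relativePairs$id2)
  expect_true(all(abs(pairIbs - mean(off)) < 3 * sd(off)))

  expect_identical(dosageMatrix(injectRelatives(g, 0, 0.5, 1)),
                   dosageMatrix(g))
  expect_error(injectRelatives(g, 1, 1.5, 1), "copyErrorRate")
})
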