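test_that("trait construction follows first/last-exam arithmetic", {
  ph <- table1Donor()                   # complete record
  ph$SBP0 <- 110; ph$SBP1 <- 125; ph$SBP2 <- 139; ph$SBP3 <- 149
  ph$AGE0 <- 39; ph$AGE1 <- 45; ph$AGE2 <- 50; ph$AGE3 <- 56
  tr <- buildTrait(LongitudinalCohort(ph), mode = "imputed")
  expect_equal(tr$dsbpDt, 39 / 17, tolerance = 1e-12)
  expect_equal(tr$age0s, 39)
  expect_equal(tr$sbp0s, 110)

  ## constant SBP -> trait 0
  ph2 <- ph
  ph2[paste0("SBP", 0:3)] <- 120
  expect_equal(buildTrait(LongitudinalCohort(ph2), mode = "imputed")$dsbpDt, 0)

  ## observed mode uses the attended exams only
  ph3 <- ph
  ph3$SBP1 <- NA; ph3$SBP3 <- NA
  ph3$MED1 <- NA; ph3$MED3 <- NA
  ph3$SMK1 <- NA; ph3$SMK3 <- NA
  tr3 <- buildTrait(LongitudinalCohort(ph3), mode = "observed")
  expect_equal(tr3$dsbpDt, (139 - 110) / (50 - 39), tolerance = 1e-12)

  ## a single attended exam is excluded with a warning
  ph4 <- ph
  ph4$ID <- "T2DGXXXXXXX"
  ph4[paste0("SBP", 1:3)] <- NA
  expect_warning(tr4 <- buildTrait(LongitudinalCohort(rbind(ph, ph4)),
                                   mode = "observed"),
                 "excluded")
  expect_equal(nrow(tr4), 1)
})

test_that("imputed-mode and observed-mode traits coincide for completers", {
  co <- simulateCohort(cohortConfig(nIndividuals = 150, nSnps = 2,
                                    dropoutMode = "mar_age", seed = 111))
  obs <- observedPhenotypes(co)
  res <- imputeCohort(obs)
  trImp <- buildTrait(imputedPhenotypes(res), mode = "imputed")
  trObs <- suppressWarnings(buildTrait(imputeAges(obs), mode = "observed"))
  cc <- individualIds(obs)[isCompleter(obs)]
  expect_equal(trImp$dsbpDt[match(cc, trImp$id)],
               trObs$dsbpDt[match(cc, trObs$id)], tolerance = 1e-12)
})

test_that("covariate screening retains real predictors and rejects noise at ~alpha", {
  set.seed(121)
  nRep <- 200
  keptNull <- keptStrong <- logical(nRep)
  for (r in seq_len(nRep)) {
    n <- 120
    trait <- data.frame(id = as.character(seq_len(n)),
                        dsbpDt = rnorm(n),
                        age0s = rnorm(n),               # pure noise
                        completer = TRUE)
    trait$sbp0s <- trait$dsbpDt * 2 + rnorm(n, 0, 0.5)  # strong signal
    ret <- suppressWarnings(
      selectCovariates(trait, candidates = c("age0s", "sbp0s")))
    keptNull[r] <- "age0s" %in% ret
    keptStrong[r] <- "sbp0s" %in% ret
  }
  expect_gt(mean(keptNull), 0.05 - 0.045)
  expect_lt(mean(keptNull), 0.05 + 0.045)
  expect_gte(mean(keptStrong), 0.99)

  ## zero-variance candidates are skipped with a warning
  trait <- data.frame(id = "1", dsbpDt = 1, age0s = 1, completer = TRUE)
  trait <- trait[rep(1, 10), ]
  trait$dsbpDt <- rnorm(10)
  w <- capture_warnings(ret <- selectCovariates(trait, candidates = "age0s"))
  expect_match(w, "zero variance", all = FALSE)
  expect_match(w, "unadjusted", all = FALSE)
  expect_length(ret, 0)
})

test_that("single-marker regression matches the normal-equations oracle", {
  set.seed(131)
  for (rep in 1:15) {
    n <- 10
    trait <- data.frame(id = sprintf("IND%05d", 1:n),
                        dsbpDt = rnorm(n), age0s = rnorm(n, 45, 10))
    d <- matrix(rbinom(n, 2, 0.4), 1, n,
                dimnames = list("snp00001", trait$id))
    g <- GenotypeData(d, data.frame(chrom = 1L, pos = 1L, alleles = "A/G"))
    sc <- singleMarkerScan(trait, g, covariates = "age0s")
    X <- cbind(1, trait$age0s, d[1, ])
    o <- oracleOls(X, trait$dsbpDt)
    expect_equal(sc$beta, unname(o$beta[3]), tolerance = 1e-10)
    expect_equal(sc$se, unname(o$se[3]), tolerance = 1e-10)
    expect_equal(sc$p, unname(o$p[3]), tolerance = 1e-10)
  }
})

test_that("monomorphic or rank-deficient SNPs yield NA results", {
  n <- 30
  trait <- data.frame(id = sprintf("IND%05d", 1:n), dsbpDt = rnorm(n))
  d <- rbind(snp00001 = rep(1, n), snp00002 = rbinom(n, 2, 0.4))
  colnames(d) <- trait$id
  g <- GenotypeData(d, data.frame(chrom = c(1L, 1L), pos = c(1L, 2L),
                                  alleles = c("A/G", "C/T")))
  sc <- singleMarkerScan(trait, g)
  expect_true(is.na(sc$p[1]))
  expect_false(is.na(sc$p[2]))
})

test_that("genomic inflation is definitional and scales with the statistics", {
  expect_equal(genomicInflation(rep(0.5, 200)), 1.0, tolerance = 1e-12)

  set.seed(141)
  chi <- rchisq(5000, 1)
  pNull <- pchisq(chi, 1, lower.tail = FALSE)
  expect_lt(abs(genomicInflation(pNull) - 1), 0.15)
  pInflated <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomicInflation(pInflated), 2 * genomicInflation(pNull),
               tolerance = 1e-10)
  expect_error(genomicInflation(numeric(0)), "no p-values")
})

test_that("interaction SSEs and F match a brute-force two-fit oracle", {
  set.seed(151)
  for (rep in 1:15) {
    n <- sample(30:60, 1)
    x1 <- rbinom(n, 2, 0.3)
    x2 <- rbinom(n, 2, 0.4)
    y <- rnorm(n) + 0.3 * x1 + 0.2 * x1 * x2
    it <- interactionTest(y, x1, x2)
    oA <- oracleOls(cbind(1, x1, x2), y)
    oAI <- oracleOls(cbind(1, x1, x2, x1 * x2), y)
    expect_equal(it$sseA, oA$sse, tolerance = 1e-10)
    expect_equal(it$sseAI, oAI$sse, tolerance = 1e-10)
    f <- (oA$sse - oAI$sse) / (oAI$sse / (n - 4))
    expect_equal(it$f, f, tolerance = 1e-10)
    expect_equal(it$p, pf(f, 1, n - 4, lower.tail = FALSE), tolerance = 1e-10)
    expect_equal(it$beta12, unname(oAI$beta[4]), tolerance = 1e-10)
    ## structural invariants
    expect_lte(it$sseAI, it$sseA)
    expect_gte(it$tRatio, 0)
    expect_lt(it$tRatio, 1)
  }
})

test_that("a trait with zero partial interaction effect gives t = 0, p = 1", {
  set.seed(161)
  n <- 50
  x1 <- rbinom(n, 2, 0.3)
  x2 <- rbinom(n, 2, 0.4)
  y <- rnorm(n)
  ## project the interaction signal out of y analytically
  XA <- cbind(1, x1, x2)
  r12 <- x1 * x2 - XA %*% solve(crossprod(XA), crossprod(XA, x1 * x2))
  yOrth <- y - drop(r12 %*% (sum(r12 * y) / sum(r12^2)))
  it <- interactionTest(yOrth, x1, x2)
  expect_equal(it$sseA, it$sseAI, tolerance = 1e-10)
  expect_equal(it$tRatio, 0, tolerance = 1e-10)
  expect_equal(it$p, 1, tolerance = 1e-8)

  ## constant dosage makes the fit rank-deficient -> NA
  expect_true(is.na(interactionTest(y, rep(1, n), x2)$p))
})

test_that("the pair scan enumerates deterministically and is chunk-invariant", {
  set.seed(171)
  n <- 40
  m <- 25
  trait <- data.frame(id = sprintf("IND%05d", 1:n), dsbpDt = rnorm(n))
  d <- matrix(rbinom(m * n, 2, 0.3), m, n,
              dimnames = list(sprintf("snp%05d", 1:m), trait$id))
  g <- GenotypeData(d, data.frame(chrom = rep(1L, m), pos = seq_len(m),
                                  alleles = rep("A/G", m)))
  sc <- interactionScan(trait, g, minMaf = 0.05, topK = 1000)
  expect_equal(attr(sc, "nPairsTested"),
               choose(sum(pmin(rowMeans(d) / 2, 1 - rowMeans(d) / 2) >= 0.05), 2))
  for (chunk in c(7L, 50L, 100000L)) {
    sc2 <- interactionScan(trait, g, minMaf = 0.05, topK = 1000,
                           chunkSize = chunk)
    expect_equal(sc, sc2, ignore_attr = TRUE)
  }
  ## top-K honoured
  sc3 <- interactionScan(trait, g, minMaf = 0.05, reportBelow = 0, topK = 5)
  expect_equal(nrow(sc3), 5)
  expect_equal(sc3$p, sort(sc$p)[1:5], tolerance = 1e-12)
})
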