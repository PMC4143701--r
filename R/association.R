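#' @include AllClasses.R
NULL

#' Build the blood-pressure progression trait table
#'
#' The trait is the annual change in systolic blood pressure,
#' `dSBP/dt` (mm Hg/year), between the first and last exams used, with
#' candidate covariates: the first non-missing AGE/SBP/MED/SMK values
#' (starred baselines), the analogous MED and SMK changes, and sex.
#'
#' In `"imputed"` mode (complete records expected) the trait uses exams 0
#' and 3; in `"observed"` mode it uses each individual's first and last
#' attended exams, requiring at least two.  Individuals with a
#' non-positive elapsed time are excluded with a warning.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @param mode `"imputed"` or `"observed"`.
#' @return `data.frame` with columns `id`, `dsbpDt`, `age0s`, `sbp0s`,
#'   `med0s`, `smk0s`, `dMed`, `dSmk`, `sex`, `completer`.
#' @export
buildTrait <- function(cohort, mode = c("imputed", "observed")) {
  mode <- match.arg(mode)
  stopifnot(is(cohort, "LongitudinalCohort"))
  ph <- phenoTable(cohort)
  if (mode == "imputed")
    .stopIf(anyNA(ph[, .waveCols()]),
            "imputed mode requires complete records; run imputeCohort() first")
  firstNonMissing <- function(v) {
    m <- as.matrix(ph[, paste0(v, .EXAMS)])
    m[cbind(seq_len(nrow(m)), max.col(!is.na(m), ties.method = "first"))]
  }
  sbp <- as.matrix(ph[, paste0("SBP", .EXAMS)])
  age <- as.matrix(ph[, paste0("AGE", .EXAMS)])
  med <- as.matrix(ph[, paste0("MED", .EXAMS)])
  smk <- as.matrix(ph[, paste0("SMK", .EXAMS)])
  n <- nrow(ph)
  first <- last <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    att <- if (mode == "imputed") 1:4 else which(!is.na(sbp[i, ]))
    if (length(att) >= 2L) {
      first[i] <- att[1L]
      last[i] <- att[length(att)]
    }
  }
  usable <- !is.na(first)
  if (any(!usable))
    warning(sprintf("%d individual(s) with < 2 attended exams excluded",
                    sum(!usable)), call. = FALSE)
  ii <- which(usable)
  dt <- age[cbind(ii, last[ii])] - age[cbind(ii, first[ii])]
  badDt <- dt <= 0 | is.na(dt)
  if (any(badDt))
    warning(sprintf("%d individual(s) with non-positive elapsed time excluded",
                    sum(badDt)), call. = FALSE)
  ii <- ii[!badDt]
  dt <- dt[!badDt]
  out <- data.frame(
    id = ph$ID[ii],
    dsbpDt = (sbp[cbind(ii, last[ii])] - sbp[cbind(ii, first[ii])]) / dt,
    age0s = firstNonMissing("AGE")[ii],
    sbp0s = firstNonMissing("SBP")[ii],
    med0s = firstNonMissing("MED")[ii],
    smk0s = firstNonMissing("SMK")[ii],
    dMed = med[cbind(ii, last[ii])] - med[cbind(ii, first[ii])],
    dSmk = smk[cbind(ii, last[ii])] - smk[cbind(ii, first[ii])],
    sex = ph$SEX[ii],
    completer = isCompleter(cohort)[ii],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select covariates by univariate screening on completers
#'
#' Each candidate covariate is regressed against the trait over completers;
#' candidates with a slope p-value below `alpha` are retained for the
#' association scan.  Zero-variance candidates are skipped with a warning.
#'
#' @param trait trait table from [buildTrait()].
#' @param completers logical vector or IDs marking the completer subset
#'   (default the table's own `completer` column).
#' @param alpha retention threshold (default 0.05).
#' @param candidates candidate column names.
#' @return character vector of retained covariate names (possibly empty,
#'   with a warning).
#' @export
selectCovariates <- function(trait,
                             completers = trait$completer,
                             alpha = 0.05,
                             candidates = c("age0s", "sbp0s", "med0s",
                                            "smk0s", "dMed", "dSmk", "sex")) {
  if (is.character(completers)) completers <- trait$id %in% completers
  sub <- trait[completers, , drop = FALSE]
  .stopIf(nrow(sub) < 3L, "too few completers for covariate screening")
  retained <- character()
  for (cand in candidates) {
    x <- sub[[cand]]
    if (stats::var(x) == 0) {
      warning(sprintf("covariate %s has zero variance; skipped", cand),
              call. = FALSE)
      next
    }
    fit <- .olsFit(cbind(1, x), sub$dsbpDt)
    if (!is.null(fit) && fit$p[2] < alpha) retained <- c(retained, cand)
  }
  if (length(retained) == 0)
    warning("no covariate retained; scans will be unadjusted", call. = FALSE)
  retained
}

#' Single-marker association scan
#'
#' Per SNP, ordinary least squares of the trait on the additive dosage plus
#' the retained covariates and an intercept, over individuals with a called
#' genotype (listwise deletion).  The per-allele effect, its standard
#' error, and the 1-df t-test p-value of the dosage coefficient are
#' reported together with the SNP's map entry, sample MAF and
#' Hardy-Weinberg exact p (computed on the analyzed genotypes).  SNPs that
#' are monomorphic in the analyzed subset, or that make the design
#' rank-deficient, yield `NA` statistics.
#'
#' @param trait trait table from [buildTrait()].
#' @param geno a [GenotypeData-class] (QC'd).
#' @param covariates covariate column names, e.g. from [selectCovariates()].
#' @return `data.frame`: `snp`, `chrom`, `pos`, `alleles`, `maf`, `hweP`,
#'   `n`, `beta`, `se`, `stat`, `p`.
#' @export
singleMarkerScan <- function(trait, geno, covariates = character()) {
  stopifnot(is(geno, "GenotypeData"))
  common <- intersect(trait$id, individualIds(geno))
  .stopIf(length(common) < length(covariates) + 3L,
          "too few individuals shared between trait and genotypes")
  trait <- trait[match(common, trait$id), , drop = FALSE]
  d <- dosageMatrix(geno)[, common, drop = FALSE]
  y <- trait$dsbpDt
  Z <- as.matrix(trait[, covariates, drop = FALSE])
  map <- snpMap(geno)
  m <- nrow(d)
  beta <- se <- stat <- p <- maf <- hweP <- rep(NA_real_, m)
  nUsed <- integer(m)
  for (s in seq_len(m)) {
    x <- d[s, ]
    ok <- !is.na(x) & !is.na(y)
    if (ncol(Z) > 0) ok <- ok & stats::complete.cases(Z)
    nUsed[s] <- sum(ok)
    xs <- x[ok]
    if (nUsed[s] > 0) {
      af <- mean(xs) / 2
      maf[s] <- min(af, 1 - af)
      counts <- tabulate(xs + 1L, nbins = 3L)
      hweP[s] <- hweExactTest(counts[1], counts[2], counts[3])
    }
    if (nUsed[s] < ncol(Z) + 3L || stats::var(xs) == 0) next
    X <- cbind(1, Z[ok, , drop = FALSE], dosage = xs)
    fit <- .olsFit(X, y[ok])
    if (is.null(fit)) next
    j <- ncol(X)
    beta[s] <- fit$beta[j]
    se[s] <- fit$se[j]
    stat[s] <- fit$t[j]
    p[s] <- fit$p[j]
  }
  out <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                    alleles = map$alleles, maf = maf, hweP = hweP,
                    n = nUsed, beta = beta, se = se, stat = stat, p = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genomic-control inflation factor
#'
#' Median-based genomic control: the observed p-values are converted to
#' 1-df chi-square quantiles and the median is divided by the null median
#' `qchisq(0.5, 1) = 0.4549364`.  Lambda near 1 indicates calibrated
#' tests; values well above 1 indicate inflation.
#'
#' @param p vector of p-values (`NA` dropped); fewer than 100 triggers a
#'   warning, none is an error.
#' @return the inflation factor lambda.
#' @export
genomicInflation <- function(p) {
  p <- p[!is.na(p)]
  .stopIf(length(p) == 0L, "no p-values supplied")
  if (length(p) < 100L)
    warning("fewer than 100 p-values; lambda estimate is unstable",
            call. = FALSE)
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
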