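#' @include AllClasses.R
NULL

#' Pairwise identity-by-state matrix
#'
#' For each pair of individuals, over the SNPs called in both: a SNP with
#' dosages `a`, `b` shares `2 - |a - b|` of its 2 alleles, and the IBS value
#' is the total shared alleles divided by the total alleles compared
#' (2 per shared SNP).  The diagonal is 1.  A pair with no jointly called
#' SNP gets `NA` (excluded from the mean/SD summaries downstream).
#'
#' @param geno a [GenotypeData-class] with at least 2 individuals.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
ibsMatrix <- function(geno) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosageMatrix(geno)
  n <- ncol(d)
  .stopIf(n < 2L, "need at least 2 individuals")
  ibs <- matrix(NA_real_, n, n, dimnames = list(colnames(d), colnames(d)))
  diag(ibs) <- 1
  for (i in seq_len(n - 1L)) {
    di <- d[, i]
    for (j in (i + 1L):n) {
      ok <- !is.na(di) & !is.na(d[, j])
      m <- sum(ok)
      if (m == 0L) next
      shared <- sum(2 - abs(di[ok] - d[ok, j]))
      ibs[i, j] <- ibs[j, i] <- shared / (2 * m)
    }
  }
  ibs
}

## call rate per individual
.sampleCallRate <- function(geno) colMeans(!is.na(dosageMatrix(geno)))

#' Flag related pairs from an IBS matrix
#'
#' Pairs whose IBS exceeds the threshold are flagged as cryptic relatives.
#' The threshold is either an absolute IBS value (default 0.84) or
#' `mean + k * SD` of the off-diagonal IBS distribution (`mode = "sd"`,
#' `k` default 14).  From each flagged pair the member with the lower
#' genotyping call rate is listed for removal; at equal call rates the
#' larger ID is removed.
#'
#' @param ibs symmetric IBS matrix from [ibsMatrix()].
#' @param geno the matching [GenotypeData-class] (for call rates).
#' @param mode `"absolute"` or `"sd"`.
#' @param threshold absolute IBS cutoff (mode `"absolute"`).
#' @param k SD multiplier (mode `"sd"`).
#' @return list with `flagged` (`data.frame`: `id1`, `id2`, `ibs`),
#'   `remove` (character IDs), `ibsMean`, `ibsSd`.
#' @export
flagRelated <- function(ibs, geno, mode = c("absolute", "sd"),
                        threshold = 0.84, k = 14) {
  mode <- match.arg(mode)
  off <- ibs[upper.tri(ibs)]
  ibsMean <- mean(off, na.rm = TRUE)
  ibsSd <- stats::sd(off, na.rm = TRUE)
  cut <- if (mode == "absolute") threshold else ibsMean + k * ibsSd
  idx <- which(upper.tri(ibs) & !is.na(ibs) & ibs > cut, arr.ind = TRUE)
  ids <- rownames(ibs)
  cr <- .sampleCallRate(geno)[ids]
  flagged <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                        ibs = ibs[idx], stringsAsFactors = FALSE)
  remove <- character()
  for (r in seq_len(nrow(flagged))) {
    a <- flagged$id1[r]; b <- flagged$id2[r]
    drop <- if (cr[a] < cr[b]) a else if (cr[b] < cr[a]) b else max(a, b)
    remove <- union(remove, drop)
  }
  list(flagged = flagged, remove = remove, ibsMean = ibsMean, ibsSd = ibsSd)
}

#' Sample missingness filter
#'
#' Lists individuals whose proportion of missing genotype entries strictly
#' exceeds `maxMissing` (default 0.40).
#'
#' @param geno a [GenotypeData-class].
#' @param maxMissing maximum tolerated missing proportion.
#' @return character vector of IDs to remove.
#' @export
sampleMissingnessFilter <- function(geno, maxMissing = 0.40) {
  stopifnot(is(geno, "GenotypeData"))
  miss <- colMeans(is.na(dosageMatrix(geno)))
  names(miss)[miss > maxMissing]
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test on genotype counts: the p-value is the total
#' probability, under the conditional distribution of the heterozygote
#' count given the allele counts, of all heterozygote counts whose
#' probability does not exceed that of the observed one.  Probabilities are
#' computed by the standard recurrence over heterozygote counts.
#'
#' @param nAA,nAB,nBB genotype counts (B the minor allele).
#' @return p-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)
#' hweExactTest(50, 0, 50)
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  stopifnot(nAA >= 0, nAB >= 0, nBB >= 0)
  n <- nAA + nAB + nBB
  if (n == 0L) return(1)
  nB <- min(2L * nBB + nAB, 2L * n - (2L * nBB + nAB))  # minor-allele count
  hets <- seq(nB %% 2L, nB, by = 2L)
  nh <- length(hets)
  probs <- numeric(nh)
  ## anchor the recurrence at the modal heterozygote count so relative
  ## probabilities never overflow, then recurse in both directions:
  ## P(h-2)/P(h) = h(h-1) / (4 (homB+1)(homA+1)),
  ## P(h+2)/P(h) = 4 homB homA / ((h+1)(h+2))
  midIdx <- which.min(abs(hets - nB * (2 * n - nB) / (2 * n)))
  probs[midIdx] <- 1
  if (midIdx > 1L) for (idx in (midIdx - 1L):1L) {
    h <- hets[idx + 1L]
    homB <- (nB - h) / 2
    homA <- n - h - homB
    probs[idx] <- probs[idx + 1L] * h * (h - 1) / (4 * (homB + 1) * (homA + 1))
  }
  if (midIdx < nh) for (idx in (midIdx + 1L):nh) {
    h <- hets[idx - 1L]
    homB <- (nB - h) / 2
    homA <- n - h - homB
    probs[idx] <- probs[idx - 1L] * 4 * homB * homA / ((h + 1) * (h + 2))
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(nAB, hets)]
  if (is.na(pObs)) stop("genotype counts inconsistent with allele count")
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

#' Per-SNP quality-control filters
#'
#' Computes, per SNP on called genotypes of the (already sample-filtered)
#' matrix: call rate, minor allele frequency and the Hardy-Weinberg exact
#' p-value, and removes SNPs with call rate `< minCallrate`, HWE
#' `p < hweAlpha`, or `MAF < minMaf` (all strict, in that reason order;
#' retained membership does not depend on the order).
#'
#' @param geno a [GenotypeData-class].
#' @param minCallrate minimum SNP call rate (default 0.99).
#' @param hweAlpha Hardy-Weinberg exclusion threshold (default 1e-6).
#' @param minMaf minimum minor allele frequency (default 0.01).
#' @return list with `snpInfo` (`data.frame`: `snp`, `chrom`, `pos`,
#'   `alleles`, `callRate`, `maf`, `hweP`) and `removed`
#'   (`data.frame`: `snp`, `reason`).
#' @export
snpFilters <- function(geno, minCallrate = 0.99, hweAlpha = 1e-6,
                       minMaf = 0.01) {
  stopifnot(is(geno, "GenotypeData"))
  d <- dosageMatrix(geno)
  n <- ncol(d)
  callRate <- rowMeans(!is.na(d))
  stats <- t(apply(d, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(maf = 0, hweP = 1))
    af <- mean(x) / 2
    maf <- min(af, 1 - af)
    counts <- tabulate(x + 1L, nbins = 3L)
    c(maf = maf, hweP = hweExactTest(counts[1], counts[2], counts[3]))
  }))
  info <- cbind(snpMap(geno), callRate = callRate,
                maf = stats[, "maf"], hweP = stats[, "hweP"])
  rownames(info) <- NULL
  reason <- rep(NA_character_, nrow(info))
  reason[is.na(reason) & callRate < minCallrate] <- "snp_callrate"
  reason[is.na(reason) & info$hweP < hweAlpha] <- "hwe"
  reason[is.na(reason) & info$maf < minMaf] <- "maf"
  removed <- data.frame(snp = info$snp[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(snpInfo = info, removed = removed)
}

#' Full genotype quality control
#'
#' Applies, in order: IBS relatedness screening (removing the lower-call-
#' rate member of each flagged pair), the sample missingness filter, then
#' the per-SNP call-rate/HWE/MAF filters computed on the retained samples.
#'
#' @param geno a [GenotypeData-class].
#' @param ibsMode,ibsThreshold,ibsK see [flagRelated()].
#' @param maxMissing see [sampleMissingnessFilter()].
#' @param minCallrate,hweAlpha,minMaf see [snpFilters()].
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (a [QcReport-class]).
#' @export
applyQc <- function(geno, ibsMode = "absolute", ibsThreshold = 0.84,
                    ibsK = 14, maxMissing = 0.40, minCallrate = 0.99,
                    hweAlpha = 1e-6, minMaf = 0.01) {
  stopifnot(is(geno, "GenotypeData"))
  ibs <- ibsMatrix(geno)
  rel <- flagRelated(ibs, geno, mode = ibsMode, threshold = ibsThreshold,
                     k = ibsK)
  samplesRemoved <- data.frame(id = rel$remove,
                               reason = rep("relatedness", length(rel$remove)),
                               stringsAsFactors = FALSE)
  keep1 <- setdiff(colnames(geno), rel$remove)
  g1 <- geno[, keep1]
  missers <- sampleMissingnessFilter(g1, maxMissing)
  samplesRemoved <- rbind(samplesRemoved,
                          data.frame(id = missers,
                                     reason = rep("sample_missingness",
                                                  length(missers)),
                                     stringsAsFactors = FALSE))
  g2 <- g1[, setdiff(keep1, missers)]
  sf <- snpFilters(g2, minCallrate, hweAlpha, minMaf)
  g3 <- g2[setdiff(rownames(g2), sf$removed$snp), ]
  report <- new("QcReport",
                ibsMean = rel$ibsMean, ibsSd = rel$ibsSd,
                flaggedPairs = rel$flagged,
                samplesRemoved = samplesRemoved,
                snpsRemoved = sf$removed,
                snpInfo = sf$snpInfo,
                nSamplesKept = ncol(g3), nSnpsKept = nrow(g3))
  list(genotypes = g3, report = report)
}
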