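#' @include association.R
NULL

## permutation of r-th replicate: a pure function of (seed, r, n)
.permutationIndices <- function(seed, r, n) {
  set.seed(.replicateSeed(seed, r))
  sample.int(n)
}

#' Monte-Carlo permutation test of an association statistic
#'
#' Re-evaluates a single-marker (or two-marker interaction) test under
#' random reassignment of the trait values across individuals; covariate
#' and genotype rows stay attached to their individuals, only the trait
#' column is shuffled.  The statistic is the nested-model F for the tested
#' term (dosage, or the dosage product given both main effects), computed
#' identically for the observed data and every replicate.  `k` counts
#' replicates with a strictly larger statistic; ties are recorded but not
#' counted.  Both the plain estimator `k/N` (which can be exactly 0) and
#' the positively-biased `(k+1)/(N+1)` are reported.
#'
#' Replicate `r` is a pure function of `(seed, r)`, so runs can be extended
#' without recomputing earlier replicates, and the same seed gives every
#' evaluated hit the identical permutation stream.
#'
#' @param y trait vector.
#' @param dosage dosage vector of the tested SNP.
#' @param covariates optional numeric matrix of covariates.
#' @param dosage2 optional second dosage; when given, the tested term is
#'   the interaction `dosage * dosage2` on top of both main effects.
#' @param nReplicates number of permutation replicates (at least 1).
#' @param seed integer seed of the replicate stream.
#' @param id label carried into the result.
#' @param statOverride replace the observed statistic (diagnostic use,
#'   e.g. forcing boundary behaviour); default `NULL`.
#' @return a [PermutationResult-class].
#' @export
permuteScan <- function(y, dosage, covariates = NULL, dosage2 = NULL,
                        nReplicates, seed = 1L, id = "",
                        statOverride = NULL) {
  .stopIf(nReplicates < 1, "need at least one replicate")
  ok <- !is.na(y) & !is.na(dosage)
  if (!is.null(dosage2)) ok <- ok & !is.na(dosage2)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  y <- y[ok]; dosage <- dosage[ok]
  Z <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
  n <- length(y)
  ones <- matrix(1, n, 1)
  if (is.null(dosage2)) {
    X0 <- cbind(ones, Z)
    X1 <- cbind(X0, dosage)
  } else {
    X0 <- cbind(ones, Z, dosage, dosage2[ok])
    X1 <- cbind(X0, dosage * dosage2[ok])
  }
  p1 <- ncol(X1)
  .stopIf(n <= p1, "too few complete observations for the permutation test")
  q0 <- qr(X0); q1 <- qr(X1)
  .stopIf(q1$rank < p1 && is.null(statOverride),
          "degenerate design: observed statistic undefined; refusing to permute")
  Q0 <- qr.Q(q0); Q1 <- qr.Q(q1)
  yty <- sum(y^2)
  fStat <- function(Yp) {
    yy <- colSums(Yp^2)
    sse0 <- yy - colSums(crossprod(Q0, Yp)^2)
    sse1 <- yy - colSums(crossprod(Q1, Yp)^2)
    (sse0 - sse1) / (sse1 / (n - p1))
  }
  statObs <- if (is.null(statOverride)) fStat(cbind(y)) else statOverride

  k <- 0; ties <- 0
  blockSize <- 1000L
  done <- 0L
  while (done < nReplicates) {
    b <- min(blockSize, nReplicates - done)
    Yp <- matrix(0, n, b)
    for (j in seq_len(b))
      Yp[, j] <- y[.permutationIndices(seed, done + j, n)]
    fr <- fStat(Yp)
    k <- k + sum(fr > statObs)
    ties <- ties + sum(fr == statObs)
    done <- done + b
  }
  new("PermutationResult",
      id = as.character(id), statObserved = as.numeric(statObs),
      k = as.numeric(k), nReplicates = as.numeric(nReplicates),
      pMc = k / nReplicates,
      pMcConservative = (k + 1) / (nReplicates + 1),
      nTies = as.numeric(ties), seed = as.integer(seed))
}

#' Permutation validation of the top-ranking scan hits
#'
#' Re-evaluates the `nTop` smallest single-marker p-values with
#' [permuteScan()], all hits sharing the same replicate stream (identical
#' permutations), so their Monte-Carlo p-values are directly comparable
#' and independent of evaluation order.
#'
#' @param scan single-marker result table from [singleMarkerScan()].
#' @param trait trait table from [buildTrait()].
#' @param geno the [GenotypeData-class] used in the scan.
#' @param covariates covariate column names used in the scan.
#' @param nTop number of hits to validate.
#' @param nReplicates permutation replicates per hit.
#' @param seed integer seed shared by all hits.
#' @return list of [PermutationResult-class], one per validated hit,
#'   in scan-rank order.
#' @export
validateTopHits <- function(scan, trait, geno, covariates = character(),
                            nTop, nReplicates, seed = 1L) {
  stopifnot(is(geno, "GenotypeData"))
  if (nTop == 0L) return(list())
  ranked <- scan[order(scan$p), , drop = FALSE]
  ranked <- ranked[!is.na(ranked$p), , drop = FALSE]
  hits <- utils::head(ranked$snp, nTop)
  common <- intersect(trait$id, individualIds(geno))
  trait <- trait[match(common, trait$id), , drop = FALSE]
  d <- dosageMatrix(geno)[, common, drop = FALSE]
  Z <- if (length(covariates) > 0) as.matrix(trait[, covariates, drop = FALSE])
       else NULL
  lapply(hits, function(s)
    permuteScan(trait$dsbpDt, d[s, ], covariates = Z,
                nReplicates = nReplicates, seed = seed, id = s))
}
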