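#' @include association.R
NULL

#' Two-SNP allelic interaction test
#'
#' Compares the additive two-SNP model `M_A: y = b0 + b1 x1 + b2 x2`
#' against `M_AI: y = b0 + b1 x1 + b2 x2 + b12 x1 x2`, where `x1`, `x2`
#' are minor-allele dosages, via their residual sums of squares.  Two
#' statistics are reported: the raw SSE ratio
#' `tRatio = (SSE_A - SSE_AI)/SSE_A` in \[0, 1), and the standard
#' nested-model F, `F = (SSE_A - SSE_AI)/(SSE_AI/(n - 4))`, whose p-value
#' (from `F(1, n-4)`) is the primary p-value.  Covariates can optionally be
#' added to both nested models.
#'
#' @param y trait vector.
#' @param x1,x2 dosage vectors (`NA` allowed; listwise deletion).
#' @param covariates optional numeric matrix of covariates added to both
#'   models.
#' @return one-row `data.frame`: `n`, `sseA`, `sseAI`, `tRatio`, `f`, `p`,
#'   `beta12`, `se12`.  All statistics are `NA` when either model is
#'   rank-deficient (e.g. a constant dosage or a collinear product term).
#' @export
interactionTest <- function(y, x1, x2, covariates = NULL) {
  ok <- !is.na(y) & !is.na(x1) & !is.na(x2)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  y <- y[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  Z <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
  n <- length(y)
  nab <- data.frame(n = n, sseA = NA_real_, sseAI = NA_real_,
                    tRatio = NA_real_, f = NA_real_, p = NA_real_,
                    beta12 = NA_real_, se12 = NA_real_)
  if (n <= 4L + NCOL(Z)) return(nab)
  XA <- cbind(1, Z, x1, x2)
  XAI <- cbind(XA, x1 * x2)
  fitA <- .olsFit(XA, y)
  fitAI <- .olsFit(XAI, y)
  if (is.null(fitA) || is.null(fitAI)) return(nab)
  sseA <- fitA$sse
  sseAI <- fitAI$sse
  dfDen <- fitAI$df
  f <- (sseA - sseAI) / (sseAI / dfDen)
  j <- ncol(XAI)
  data.frame(n = n, sseA = sseA, sseAI = sseAI,
             tRatio = if (sseA > 0) (sseA - sseAI) / sseA else 0,
             f = f,
             p = stats::pf(f, 1, dfDen, lower.tail = FALSE),
             beta12 = fitAI$beta[j], se12 = fitAI$se[j])
}

#' Exhaustive two-marker interaction scan
#'
#' Enumerates all unordered pairs of SNPs meeting the interaction MAF
#' criterion (default 5%, computed on called genotypes of the analyzed
#' sample) in deterministic `(i < j)` index order and applies
#' [interactionTest()] to each.  Results are streamed in chunks so memory
#' is bounded by the chunk size rather than the pair count: a pair is kept
#' when its p-value is at most `reportBelow` or falls within the current
#' top `topK`.
#'
#' @param trait trait table from [buildTrait()].
#' @param geno a [GenotypeData-class] (QC'd).
#' @param minMaf interaction MAF criterion (default 0.05).
#' @param covariates optional covariate column names added to both nested
#'   models (default none, the printed model form).
#' @param reportBelow keep every pair with `p <= reportBelow` (default 1,
#'   i.e. keep all).
#' @param topK always keep the `topK` smallest p-values (default 100).
#' @param chunkSize pairs per processing chunk (default 20000).
#' @return `data.frame` sorted by p: `snp1`, `snp2`, `n`, `sseA`, `sseAI`,
#'   `tRatio`, `f`, `p`, `beta12`, `se12`; the attribute `nPairsTested`
#'   carries the total enumerated pair count.
#' @export
interactionScan <- function(trait, geno, minMaf = 0.05,
                            covariates = character(),
                            reportBelow = 1, topK = 100L,
                            chunkSize = 20000L) {
  stopifnot(is(geno, "GenotypeData"))
  common <- intersect(trait$id, individualIds(geno))
  trait <- trait[match(common, trait$id), , drop = FALSE]
  d <- dosageMatrix(geno)[, common, drop = FALSE]
  y <- trait$dsbpDt
  Z <- if (length(covariates) > 0) as.matrix(trait[, covariates, drop = FALSE])
       else NULL
  af <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  elig <- which(!is.na(maf) & maf >= minMaf)
  .stopIf(length(elig) < 2L, "fewer than 2 SNPs meet the interaction MAF criterion")
  m <- length(elig)
  nPairs <- m * (m - 1) / 2
  snps <- rownames(d)

  keep <- list()
  chunk <- vector("list", chunkSize)
  fill <- 0L
  ## after each chunk, retain only the report set (p <= reportBelow) plus
  ## the running top-K, so memory is bounded by the chunk size; pairs with
  ## undefined statistics (NA p) are excluded from the result set
  flush <- function(chunk, fill, keep) {
    if (fill == 0L) return(keep)
    keep[[length(keep) + 1L]] <- do.call(rbind, chunk[seq_len(fill)])
    combined <- do.call(rbind, keep)
    ord <- order(combined$p, combined$snp1, combined$snp2, na.last = NA)
    combined <- combined[ord, , drop = FALSE]
    nKeep <- max(sum(combined$p <= reportBelow), min(topK, nrow(combined)))
    list(combined[seq_len(min(nKeep, nrow(combined))), , drop = FALSE])
  }
  for (a in seq_len(m - 1L)) {
    ia <- elig[a]
    xa <- d[ia, ]
    for (b in (a + 1L):m) {
      ib <- elig[b]
      row <- interactionTest(y, xa, d[ib, ], covariates = Z)
      row <- cbind(snp1 = snps[ia], snp2 = snps[ib], row,
                   stringsAsFactors = FALSE)
      fill <- fill + 1L
      chunk[[fill]] <- row
      if (fill == chunkSize) {
        keep <- flush(chunk, fill, keep)
        fill <- 0L
      }
    }
  }
  keep <- flush(chunk, fill, keep)
  out <- keep[[1L]]
  rownames(out) <- NULL
  attr(out, "nPairsTested") <- nPairs
  out
}
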