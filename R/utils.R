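## Internal helpers: named RNG streams, fast OLS, small utilities.

## Named sub-streams derived from one user seed.  Each generator component
## seeds its own stream, so toggling (say) relative-pair injection does not
## shift the phenotype draws.  Arithmetic stays below 2^53 so the double
## computation is exact; the result is a valid 32-bit seed.
.streamSeed <- function(seed, stream) {
  streams <- c(phenotypes = 1, genotypes = 2, dropout = 3,
               relatives = 4, permutation = 5, pipeline = 6)
  off <- streams[[stream]]
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + off * 104729) %% 2147483647)
}

## Counter-based replicate seed: replicate r is a pure function of (seed, r),
## so a permutation run can be extended without recomputing earlier replicates.
.replicateSeed <- function(seed, r) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(r) * 7919) %% 2147483647)
}

## OLS via QR with coefficient table; X must include the intercept column.
## Returns NULL when the design is rank-deficient.
.olsFit <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) return(NULL)
  qrX <- qr(X)
  if (qrX$rank < p) return(NULL)
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  sse <- sum(res^2)
  df <- n - p
  Rinv <- backsolve(qr.R(qrX), diag(p))
  d <- rowSums(Rinv^2)              # diag of (X'X)^-1, pivoted column order
  d[qrX$pivot] <- d                 # back to original column order
  se <- sqrt(sse / df * d)
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       sse = sse, df = df, n = n)
}

.stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

## round() with the IEC 60559 banker's rule is fine for synthetic data,
## but calendar-year averaging follows the usual half-up convention.
.roundHalfUp <- function(x) floor(x + 0.5)
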