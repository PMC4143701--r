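## Independent brute-force oracles. These deliberately avoid the package's
## computational routes (QR fits, recurrences, vectorized distances) so that
## agreement is a real cross-check.

## OLS through the explicit normal equations
oracleOls <- function(X, y) {
  XtXinv <- solve(t(X) %*% X)
  beta <- drop(XtXinv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  se <- sqrt(sum(res^2) / df * diag(XtXinv))
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       sse = sum(res^2), df = df)
}

## scalar per-pair IBS
oracleIbs <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  sum(2 - abs(a[ok] - b[ok])) / (2 * sum(ok))
}

## HWE exact test by direct log-factorial enumeration
oracleHwe <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nB <- 2 * nBB + nAB
  nA <- 2 * n - nB
  if (nB > nA) { tmp <- nB; nB <- nA; nA <- tmp }
  hets <- seq(nB %% 2, nB, by = 2)
  lp <- sapply(hets, function(h) {
    homB <- (nB - h) / 2
    homA <- n - h - homB
    lfactorial(n) - lfactorial(homA) - lfactorial(h) - lfactorial(homB) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  })
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pObs <- p[match(nAB, hets)]
  min(1, sum(p[p <= pObs * (1 + 1e-12)]))
}

## donor distance, term by term, straight from the definition
oracleDistance <- function(nrow, crow, W, constants) {
  tot <- 0
  for (i in 0:3) for (v in c("AGE", "SBP", "MED", "SMK")) {
    col <- paste0(v, i)
    w <- switch(v, AGE = W@wAge, SBP = 1, MED = W@wMed, SMK = W@wSmk)
    s <- constants@sigma[v, i + 1]
    m <- constants@mu[v, i + 1]
    if (is.na(s) || s == 0) next
    if (is.na(nrow[[col]])) next
    tot <- tot + w * ((nrow[[col]] - m) / s - (crow[[col]] - m) / s)^2
  }
  tot
}

## complete synthetic phenotype table built directly (no generator), for
## hand-constructed imputation scenarios
handPheno <- function(n, seed = 1) {
  set.seed(seed)
  age0 <- sample(30:60, n, replace = TRUE)
  ph <- data.frame(ID = sprintf("H%03d", seq_len(n)),
                   SEX = rbinom(n, 1, 0.5),
                   BIRTH_YEAR = 1993 - age0)
  for (k in 0:3) ph[[paste0("AGE", k)]] <- age0 + c(0, 5, 10, 16)[k + 1]
  for (k in 0:3) ph[[paste0("SBP", k)]] <- round(rnorm(n, 120 + 3 * k, 12))
  for (k in 0:3) ph[[paste0("MED", k)]] <- rbinom(n, 1, 0.2 + 0.1 * k)
  for (k in 0:3) ph[[paste0("SMK", k)]] <- rbinom(n, 1, 0.3)
  ph
}

## the worked imputation example rows (non-completer with exams 0 and 3
## missing; its complete nearest donor)
table1Noncompleter <- function() {
  data.frame(ID = "T2DG2501049", SEX = 0, BIRTH_YEAR = 1954,
             AGE0 = NA, AGE1 = 45, AGE2 = 50, AGE3 = NA,
             SBP0 = NA, SBP1 = 125, SBP2 = 139, SBP3 = NA,
             MED0 = NA, MED1 = 0, MED2 = 0, MED3 = NA,
             SMK0 = NA, SMK1 = 0, SMK2 = 0, SMK3 = NA)
}

table1Donor <- function() {
  data.frame(ID = "T2DG0300150", SEX = 0, BIRTH_YEAR = 1958,
             AGE0 = 35, AGE1 = 41, AGE2 = 45, AGE3 = 51,
             SBP0 = 110, SBP1 = 121, SBP2 = 135, SBP3 = 149,
             MED0 = 0, MED1 = 0, MED2 = 0, MED3 = 1,
             SMK0 = 0, SMK1 = 0, SMK2 = 0, SMK3 = 0)
}
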