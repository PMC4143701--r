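#' @include AllClasses.R
NULL

#' Code follow-up presence patterns
#'
#' For every individual, derive the binary indicators `x1, x2, x3` that
#' equal 1 exactly when the SBP measurement of the corresponding follow-up
#' exam is present, plus an indicator for baseline SBP itself.  Presence is
#' judged from SBP alone, the variable whose dropout process is under
#' scrutiny.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @return `data.frame` with columns `id`, `x1`, `x2`, `x3`,
#'   `sbp0Observed`.
#' @examples
#' ph <- phenoTable(generatePhenotypes(cohortConfig(10, 1, seed = 1)))
#' ph$SBP2 <- NA
#' codePresence(LongitudinalCohort(ph))
#' @export
codePresence <- function(cohort) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  ph <- phenoTable(cohort)
  data.frame(
    id = ph$ID,
    x1 = as.integer(!is.na(ph$SBP1)),
    x2 = as.integer(!is.na(ph$SBP2)),
    x3 = as.integer(!is.na(ph$SBP3)),
    sbp0Observed = as.integer(!is.na(ph$SBP0))
  )
}

#' Joint regression diagnostic of the missing-data mechanism
#'
#' Regresses baseline SBP on the follow-up presence indicators,
#' `SBP0 = b0 + b1*x1 + b2*x2 + b3*x3`, over individuals with observed
#' baseline SBP, and tests `b1 = b2 = b3 = 0` with the nested-model F test.
#' A small p-value means follow-up attendance carries information about
#' baseline SBP, i.e. the data are not MCAR.  The same test is repeated
#' with baseline age as a covariate: if the unadjusted test rejects but the
#' age-adjusted one does not, age explains the dropout and MAR is the
#' plausible mechanism.  Baseline age is taken from the data and recovered
#' as `examYear0 - BIRTH_YEAR` when missing (always possible).
#'
#' Presence indicators constant across the sample are dropped with a
#' warning; if all are dropped the joint p-value is `NA`.
#'
#' @param cohort a [LongitudinalCohort-class].
#' @param alpha significance threshold used for the verdict (default 0.05).
#' @return a [MechanismReport-class].
#' @export
mcarJointTest <- function(cohort, alpha = 0.05) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  pres <- codePresence(cohort)
  ph <- phenoTable(cohort)
  keep <- pres$sbp0Observed == 1L
  dat <- data.frame(sbp0 = ph$SBP0[keep],
                    x1 = pres$x1[keep], x2 = pres$x2[keep], x3 = pres$x3[keep])
  ey0 <- .roundHalfUp(mean(ph$BIRTH_YEAR + ph$AGE0, na.rm = TRUE))
  dat$age0 <- ifelse(is.na(ph$AGE0[keep]), ey0 - ph$BIRTH_YEAR[keep],
                     ph$AGE0[keep])
  .stopIf(nrow(dat) < 5L + 5L,
          "too few individuals with observed baseline SBP (%d)", nrow(dat))

  const <- vapply(dat[c("x1", "x2", "x3")],
                  function(x) stats::var(x) == 0, logical(1))
  dropped <- names(const)[const]
  if (length(dropped) > 0)
    warning(sprintf("presence indicator(s) constant, dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  ind <- setdiff(c("x1", "x2", "x3"), dropped)

  jointP <- function(covars) {
    null_f <- stats::as.formula(paste("sbp0 ~", paste(c("1", covars), collapse = " + ")))
    full_f <- stats::as.formula(paste("sbp0 ~", paste(c("1", covars, ind), collapse = " + ")))
    full <- stats::lm(full_f, data = dat)
    if (length(ind) == 0)
      return(list(p = NA_real_, fit = as.data.frame(summary(full)$coefficients)))
    null <- stats::lm(null_f, data = dat)
    an <- stats::anova(null, full)
    list(p = an[["Pr(>F)"]][2], fit = as.data.frame(summary(full)$coefficients))
  }
  un <- jointP(character())
  ad <- jointP("age0")

  verdict <- if (is.na(un$p) || un$p >= alpha) {
    "consistent-with-MCAR"
  } else if (is.na(ad$p) || ad$p >= alpha) {
    "MAR-suspected"
  } else {
    "not-explained-by-age"
  }
  new("MechanismReport",
      pUnadjusted = un$p, pAdjusted = ad$p,
      unadjustedFit = un$fit, adjustedFit = ad$fit,
      verdict = verdict, droppedIndicators = dropped,
      nUsed = nrow(dat))
}
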