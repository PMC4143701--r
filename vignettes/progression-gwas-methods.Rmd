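---
title: "Methods: imputation-based GWAS of blood-pressure progression"
author: "progwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputation-based GWAS of blood-pressure progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progwas)
```

# The analysis problem

`progwas` analyzes the *progression* of systolic blood pressure (SBP) as a
quantitative trait in a four-wave longitudinal study: per individual,

$$\Delta SBP/\Delta t \;=\; \frac{SBP_{\text{last}} - SBP_{\text{first}}}{t_{\text{last}} - t_{\text{first}}}\quad\text{(mm Hg/year)},$$

with first/last referring either to exams 0 and 3 of a completed record or
to the first and last *attended* exams when no imputation is used.  The
obstacle is missingness: in realistic cohorts a large fraction of
individuals miss at least one wave, and dropout is typically not
independent of the data.  The pipeline therefore runs, in order:

1. a regression diagnostic of the missing-data mechanism,
2. correlation-weighted nearest-completer (hot-deck) imputation,
3. genotype quality control,
4. a single-marker additive GWAS of $\Delta SBP/\Delta t$ with
   genomic-control monitoring,
5. an exhaustive two-SNP allelic-interaction scan, and
6. Monte-Carlo permutation validation of top hits.

Every stage is exercised against a synthetic cohort generator with known
ground truth, so all operating characteristics quoted below are computed,
not asserted.

# Missingness diagnostics

For each individual, let $x_i \in \{0,1\}$ indicate whether the SBP
measurement of follow-up exam $i$ ($i = 1,2,3$) is present.
`mcarJointTest()` fits

$$SBP_0 = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3 x_3 (+ \gamma\, AGE_0)$$

over individuals with observed baseline SBP and tests
$\beta_1=\beta_2=\beta_3=0$ with the standard nested-model F test.  Under
MCAR, attendance carries no information about baseline SBP and the test is
a null test; a rejection that *disappears* once baseline age enters the
model is the signature of age-driven MAR dropout.  Design choices:

* The model's outcome is $SBP_0$, so the test sample is restricted to
  individuals with observed baseline SBP — the only reading under which
  the regression is estimable.  Baseline age is recovered from birth year
  when unobserved (always possible).
* The joint test is a nested-model F test; indicators constant across the
  sample are dropped with a warning, and when all are constant the joint
  p-value is reported as `NA` rather than invented.
* The verdict has three levels.  The rule "unadjusted $p < \alpha$,
  adjusted $p \ge \alpha$" labels MAR-suspected; an unadjusted
  non-rejection is consistent-with-MCAR; and when both tests reject we
  report `not-explained-by-age` rather than force the two-level
  dichotomy onto an unlabeled case.

The test can never separate MAR from MNAR: a dropout process driven by
the *current, unobserved* SBP can produce the same observable pattern.
The generator's `mnar_sbp` mode exists precisely to emulate that
indistinguishable case.

# Hot-deck imputation

Imputation proceeds in six steps on the wide table of
$AGE_i, SBP_i, MED_i, SMK_i$ ($i=0..3$; medication and smoking are 0/1):

1. **Exam calendar years.** Each attended exam contributes
   $BIRTH\_YEAR + AGE_i$; the per-exam average is rounded to a whole year
   (ages are integer years throughout, matching field convention).
2. **Age completion.** Missing $AGE_i \leftarrow$ exam year $-$ birth
   year.  After this step age indicators are all 1.
3. **Weights.** Over completers, with $\Delta SBP = SBP_3 - SBP_0$
   (deliberately *not* divided by time — this is the step-3 quantity, not
   the trait): $\alpha_1, \alpha_2, \alpha_3$ are the Pearson correlations
   of $\Delta SBP$ with $AGE_0, MED_0, SMK_0$, and $\beta$ with $SBP_0$.
4. **Distance.** For non-completer $N$ and completer $C$,
   $$d(C,N) = \sum_{i=0}^{3}\Big[\,w_a(\widehat{AGE}_i^N-\widehat{AGE}_i^C)^2
   + I_{SBP_i^N}(\widehat{SBP}_i^N-\widehat{SBP}_i^C)^2
   + w_m I_{MED_i^N}(\widehat{MED}_i^N-\widehat{MED}_i^C)^2
   + w_s I_{SMK_i^N}(\widehat{SMK}_i^N-\widehat{SMK}_i^C)^2\Big]$$
   where hats denote normalized values and $I$ is the non-completer's
   presence indicator (donors are complete by construction).
5. **Donor choice.** The completer minimizing $d$; exact ties break to the
   lexicographically smallest donor ID and are recorded in the audit
   table.
6. **Transfer.** Missing $SBP/MED/SMK$ slots are copied from the donor at
   the same exam; observed values are never overwritten, and ages come
   from step 2, not from the donor.

Numerical and design choices that the distance definition leaves open:

* **Normalization population.** Means and SDs are computed per variable
  and exam over *all* individuals with the value observed there, and the
  same constants normalize completers and non-completers.  A distance
  compares a completer against a non-completer, so both must live on one
  scale; normalizing each group by its own moments would make the
  squared differences incommensurable.  The SD is the population form
  $\sqrt{\overline{x^2}-\bar{x}^2}$.
* **Absolute-value weights.** The raw ratios $\alpha_k/\beta$ can be
  negative, and a negative weight on a squared difference destroys the
  metric property, so the weights are $w = |\alpha_k/\beta|$.  The SBP
  term carries implicit weight 1 and weights are not renormalized.
* **Degeneracies.** A zero-variance predictor gets correlation 0 (weight
  0, with a warning); $|\beta| < 10^{-8}$ is a hard error since every
  weight is then undefined; a zero SD in a needed term drops that term
  with a warning.  Binary variables are normalized exactly like
  continuous ones — the definition makes no exception, and the weight
  ratio absorbs the scale.
* **Sex** does not enter the distance; a `sameSexDonors` flag can
  restrict the donor pool instead (off by default).

`imputeCohort()` is idempotent on complete tables, never changes an
observed value, and emits an audit table (donor, distance, tie flag,
imputed slots) from which donor consistency is machine-checkable.

# Genotype quality control

* **Relatedness.** Pairwise IBS over jointly called SNPs
  ($\text{shared alleles}=2-|d_a-d_b|$ per SNP, divided by 2 per shared
  SNP; counting SNPs or alleles gives the identical ratio).  Pairs above
  an absolute threshold (default 0.84) — or `mean + k·SD` with $k=14$ in
  the alternative mode — are flagged, and the member with the lower call
  rate is removed (ties: larger ID).
* **Sample missingness.** Strictly more than 40% missing entries removes
  the individual.
* **SNP filters** on the retained samples: call rate $<$ 99%, HWE exact
  $p < 10^{-6}$, or MAF $<$ 1% (all strict, reasons recorded in the order
  call rate → HWE → MAF; the retained set is order-independent).  The
  Hardy-Weinberg test is the exact conditional test on the heterozygote
  count, computed by the modal-anchored probability recurrence so that
  relative probabilities never overflow; chi-square approximations
  misbehave exactly at the low MAFs the filter must police.

# Association scans

**Single marker.** Per SNP, OLS of the trait on minor-allele dosage plus
retained covariates and an intercept, with listwise deletion per SNP; the
1-df t-test on the dosage coefficient is the reported p-value (at these
sample sizes t and Wald-$\chi^2$ are numerically indistinguishable; t is
used).  Covariate candidates are the starred baselines
($AGE_0^*, SBP_0^*, MED_0^*, SMK_0^*$ = first non-missing values), the
medication and smoking changes, and sex; each is screened univariately on
completers at $\alpha = 0.05$.  Genomic control uses the median-based
estimator $\lambda = \mathrm{med}\,\chi^2_1 / 0.4549$.

**Interaction.** For SNP pair $(1,2)$ the additive model
$M^A: y=\beta_0+\beta_1x_1+\beta_2x_2$ is compared with
$M^{A,I}$ adding $\beta_{12}x_1x_2$.  Two statistics are reported: the
raw SSE ratio $t = (SSE^A - SSE^{A,I})/SSE^A \in [0,1)$, and the standard
nested-model $F = (SSE^A - SSE^{A,I})/(SSE^{A,I}/(n-4))$ with p-values
from $F(1, n-4)$.  The ratio $t$ is *not* F-distributed on
$(n-4, 1)$ degrees of freedom — it lacks the degrees-of-freedom scaling
and inverts the numerator/denominator roles — so using it as stated would
destroy calibration; the standard F is the evident intent of an
SSE-comparison test and is the primary p-value.  Both nested models are
fitted without covariates by default (the printed model form); a flag
adds the retained covariates to both.  The pair enumeration is
deterministic ($i<j$ in index order), streamed in chunks with a
report-threshold plus top-K retention so memory is bounded by the chunk
size, not the pair count.

**Permutation.** Top hits are re-evaluated by uniformly permuting the
trait column only — covariates and genotypes stay attached to their
individuals — and recomputing the identical nested-F statistic.  With $k$
replicates strictly exceeding the observed statistic, both $k/N$ (which
can be exactly 0, the convention used for reporting overwhelming
signals) and the positively-biased $(k+1)/(N+1)$ are reported; ties are
logged and not counted.  Replicate $r$ is a pure function of
$(\text{seed}, r)$, so runs extend without recomputation and all hits of
one validation share the identical permutation stream.  Whether the
covariate rows should be permuted jointly with the trait is genuinely
open; trait-only shuffling preserves the covariate-genotype association
structure and is the recorded choice.

# The synthetic cohort generator

`simulateCohort()` emulates a four-wave study on the calendar schedule
1993/1998/2003/2009 with per-individual integer jitter (±2 years,
clamped so ages stay strictly increasing).  The SBP model is

$$SBP_{ik} = \mu + 0.5\,AGE_{0i} + 5\,\text{male}_i + b_i
+ s_i\,(AGE_{ik}-AGE_{i0}) + \varepsilon_{ik},$$

with person-level intercept $b_i\sim N(0, 10^2)$ mm Hg (the source of
within-person tracking that makes hot-deck donor matching informative),
latent slope $s_i \sim N(0.5 + 0.01\,(AGE_{0i}-45),\,0.4^2)$ mm Hg/year,
and exam noise $\varepsilon \sim N(0, 8^2)$ mm Hg — magnitudes chosen as
typical for adult SBP visit-to-visit variability.  Medication uptake is a
persistent logistic function of current SBP (centered at 140 mm Hg);
smoking is a highly persistent binary state.  All constants live in
`generatorDefaults()` and are config-overridable.

Planted genetic effects add `effect × dosage` (or
`effect × dosage₁ × dosage₂`) to the latent slope *before* SBP values are
materialized, and materialization reuses the identical latent noise — so
a zero effect is bit-identical to no effect, and noiseless settings give
exact group-mean separations.  Dropout masks whole waves: attendance of
each follow-up is Bernoulli with
$\text{logit}(p) = \text{logit}(0.75) - \text{strength}\cdot(\text{predictor}-\text{center})$,
the predictor being baseline age (`mar_age`), current SBP (`mnar_sbp`) or
a constant (`mcar`); patterns are non-monotone and exam 0 is exempt by
default.  The default base attendance of 0.75 per wave yields roughly
half non-completers, in the middle of the 30–70% band typical of
long-running cohorts; per-wave dropout rates of the motivating design are
not publicly documented, so these defaults are chosen, not calibrated.
Cryptic relatives are injected by near-copying genotype vectors with a
per-SNP resampling probability.  A single seed feeds named sub-streams
(phenotypes, genotypes, dropout, relatives), so toggling one component
never shifts another's draws.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent), pedigree structure beyond duplicated pairs, measurement
feedback of medication onto SBP, diastolic pressure or hypertension
status.  Passing calibration and recovery tests on this generator shows
the *estimators* behave as designed; it cannot certify behaviour under LD,
population stratification, or treatment feedback.

# Verification experiments and problem sizes

The test suite computes, among others (sizes chosen to keep the full
suite within a few minutes while leaving Monte-Carlo error well inside
the asserted margins):

* exact worked-example checks of donor argmin selection and value
  transfer;
* oracle equivalence (≤ $10^{-10}$ relative) of the distance, IBS, OLS,
  HWE-exact and interaction-SSE computations against independent
  brute-force implementations, 100 random instances each;
* type-I error within $0.05 \pm 0.015$ and $\lambda \in [0.85, 1.15]$ on
  null scans (n = 300; 2000 SNPs; 5151 pairs) run through the full
  dropout-imputation-scan pipeline;
* recovery of a planted 1.0 mm Hg/year per-allele effect (MAF 0.2,
  n = 300, 100 replicates) with |bias| < 0.05 and ~95% CI coverage, and
  first-rank recovery of a planted 2.0 interaction among 50 null SNPs in
  ≥ 90% of 50 replicates;
* hot-deck SBP RMSE ≤ per-exam-mean RMSE on an identical ~40% MAR mask,
  with exam-wise mean shifts < 0.15 SD;
* the MAR diagnostic signature (unadjusted rejection, adjusted
  uniformity) over 200 replicates;
* permutation/parametric agreement within 3 Monte-Carlo standard errors
  at MAF 0.3, n = 300, $10^5$ replicates.

One methodological note from the recovery experiment: the univariate
covariate screen will happily retain the *medication change* covariate,
which in the generator is a downstream consequence (mediator) of any
genetic effect on the SBP slope; conditioning on it attenuates the
effect estimate.  The recovery experiment therefore adjusts for the
baseline covariates and sex only.  In real analyses the same caution
applies to any covariate measured after baseline.

# Known limitations

* Hot-deck imputation is single imputation: downstream standard errors
  ignore imputation uncertainty.  Multiple imputation would quantify it
  and is out of scope by design.
* The diagnostic cannot distinguish MAR from MNAR; `mnar_sbp` cohorts
  exist to study the consequences, not to detect them.
* The pair scan is a correct, memory-bounded enumerator validated at
  desk scale; genome-scale pair counts ($10^{10}$+) need compiled or
  distributed execution beyond this package's scope.
* The permutation engine caps at ~$10^5$–$10^6$ replicates; reporting
  $k/N = 0$ at such $N$ bounds the p-value rather than estimating it,
  which is why $(k+1)/(N+1)$ is always reported alongside.
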