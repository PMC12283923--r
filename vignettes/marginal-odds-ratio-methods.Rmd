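---
title: "Estimating a marginal odds ratio from observational cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a marginal odds ratio from observational cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalor)
```

## The problem

causalor estimates the causal effect of a binary exposure (diabetes
mellitus, `A`) on a binary outcome (all-cause death within five years of
breast-cancer surgery, `Y`) from an observational cohort in which the
exposure was not randomized.  Exposed and unexposed patients differ
systematically — diabetic patients are older, heavier, and present at more
advanced stage — so the crude mortality contrast mixes the effect of the
exposure with the effect of those covariates.

The estimand is the **marginal odds ratio** contrasting the two mean
potential outcomes,

$$
\mathrm{OR} \;=\;
\frac{E[Y(1)]\,\{1 - E[Y(0)]\}}{\{1 - E[Y(1)]\}\,E[Y(0)]},
$$

where $Y(a)$ is the outcome a patient would have had under exposure level
$a$.  This is a population-level ("marginal") quantity: it is **not** the
conditional odds ratio from a multivariable logistic regression, and for a
non-null effect the two differ because the odds ratio is non-collapsible.
Identification rests on the usual three assumptions: no interference and a
single exposure version (SUTVA), positivity (every covariate profile has
positive probability of both exposure levels), and no unmeasured
confounding given the adjustment set.  The adjustment set is the eleven
clinical covariates: age, BMI, Ki67, P53, stage, HER2, ER, PR, lymphatic
metastasis, hypertension, and menopause status.

## The four estimators

All four estimators reduce to estimates $\hat\psi_1$ of $E[Y(1)]$ and
$\hat\psi_0$ of $E[Y(0)]$, mapped through the estimand formula by
`marginal_or()`.

**G-computation** (`estimate_gc`) fits an outcome regression
$Q(A,W) = P(Y=1 \mid A, W)$ — by default a main-effects logistic model —
and standardizes: $\hat\psi_a = n^{-1}\sum_i \hat Q(a, W_i)$.  It is
consistent when the outcome model is correct.

**IPTW** (`estimate_iptw`) fits a propensity score
$g(W) = P(A=1 \mid W)$ and weights each patient by the inverse
probability of the exposure actually received,
$w_i = A_i/\hat g(W_i) + (1-A_i)/(1-\hat g(W_i))$.  We use the Hajek
(weight-normalized) form, $\hat\psi_1 = \sum_i A_i w_i Y_i / \sum_i A_i
w_i$, rather than the Horvitz–Thompson form: the Hajek mean is invariant
to weight rescaling and always lies in $[0,1]$.  A stabilized-weight
variant would change nothing here precisely because of that
normalization.  It is consistent when the propensity model is correct.

**TMLE** (`estimate_tmle`, parametric mode) starts from the
G-computation fit and performs one targeted fluctuation.  With clever
covariates $H_1 = A/\hat g(W)$ and $H_0 = (1-A)/(1-\hat g(W))$, a
no-intercept logistic regression of $Y$ on $(H_1, H_0)$ with offset
$\mathrm{logit}\,\hat Q(A,W)$ yields $(\hat\varepsilon_1,
\hat\varepsilon_0)$, and the updated predictions are
$\hat Q^*(a,W) = \mathrm{expit}\{\mathrm{logit}\,\hat Q(a,W) +
\hat\varepsilon_a H_a(a,W)\}$.  At the fitted fluctuation the empirical
mean of the efficient influence curve (EIC)

$$
D_a(O) = H_a(A,W)\,\{Y - \hat Q^*(A,W)\} + \hat Q^*(a,W) - \hat\psi_a
$$

is zero — the targeting property, asserted in the test suite at
$10^{-8}\,\mathrm{SD}(D)$.  TMLE is doubly robust: consistent if either
the outcome or the propensity model is correct.

We use a two-epsilon fluctuation (separate $\varepsilon_1, \varepsilon_0$
on the two clever covariates) rather than a single epsilon on a signed
covariate; both solve the EIC score equation, and the two-parameter form
decouples the arms, which keeps the update well-behaved when one arm is
small.

**TMLE-SL** replaces both parametric nuisance fits with a
cross-validated **super learner**: 15-fold stratified cross-validation
over six base learners — random forest, k-nearest neighbours, an
RBF-kernel SVM, elastic-net logistic regression, and two
gradient-boosted-tree configurations (shallow trees with moderate
shrinkage and deeper trees with slower shrinkage) — with convex weights
chosen to minimize the cross-validated negative Bernoulli log-likelihood
of the weighted combination.  The weight solver works on a softmax
reparameterization of the simplex, started both from uniform weights and
from the single best learner, so the ensemble's CV risk can never exceed
the best single learner's (asserted to $10^{-8}$).  The SVM has no native
probabilities; Platt scaling is fitted inside each training fold
(kernlab's internal 3-fold scheme), so no held-out information leaks into
the calibration.

## Confidence intervals

Following standard practice for these estimators, GC, IPTW and
parametric TMLE get **nonparametric percentile bootstrap** intervals
(default $B = 1000$): patients are resampled with replacement and the
*entire* pipeline — including all nuisance fits — is re-run per
replicate, so nuisance-estimation uncertainty propagates.  Replicates
that fail (separation, an empty arm, a zero counterfactual mean) are
dropped and counted; more than 5% failures is an error rather than a
silently narrowed interval.  TMLE-SL gets an **efficient influence
curve** interval: the delta method maps the per-arm EICs to the EIC of
the log odds ratio,
$D_{\log\mathrm{OR}} = D_1/\{\psi_1(1-\psi_1)\} -
D_0/\{\psi_0(1-\psi_0)\}$, and the interval is
$\exp\{\log\widehat{\mathrm{OR}} \pm 1.96\,\mathrm{SD}(D_{\log
\mathrm{OR}})/\sqrt n\}$.  Building the interval on the log scale keeps
it positive and matches the asymptotics; the test suite checks that the
two constructions agree within 20% on a well-specified cohort of
$n = 5000$.

## The synthetic cohort generator

The analyzed cohort is not publicly deposited, so the package ships a
generator (`generator_spec()`, `generate_cohort()`) whose structural
equations are known, making every estimator testable by parameter
recovery.  The defaults emulate the reference cohort's printed
marginals:

* $n = 3386$; covariates drawn independently with age
  $\sim N(51, 10.4^2)$ and BMI $\sim N(23.9, 3.3^2)$ (clamped to 25–85
  years and 15–40 kg/m², the plausible clinical ranges — the clamp also
  bounds the true propensity inside $(0.01, 0.99)$); Bernoulli rates for
  the eight binary covariates taken from the cohort's overall
  frequencies (e.g. lymphatic metastasis 68.78%, Ki67 41.08%); stage
  I/II/III probabilities 45.33/40.64/14.03%.  Hypertension prevalence is
  not reported in the source table; 25% is a realistic rate for a cohort
  of this age profile.
* exposure from a logistic propensity model in which age, BMI,
  hypertension and stage raise diabetes risk; the intercept is
  calibrated by Monte-Carlo root-solving so the marginal exposure
  prevalence is 8.86%;
* outcome from a logistic structural model in which age, BMI, stage,
  lymphatic metastasis, Ki67, P53 and hypertension raise and ER/PR lower
  death risk; intercept and exposure coefficient jointly calibrated so
  the marginal 5-year mortality is 6.35% and the **true marginal OR is
  1.9**, the neighbourhood of the estimates reported for the reference
  cohort.  The 1.9 is a documented design choice for realistic recovery
  tests, not a reproduction target.

`true_marginal_effect()` computes the known truth by averaging the
structural outcome probabilities over $10^6$ covariate draws
(Monte-Carlo SE of each mean $< 10^{-3}$); the test suite cross-checks
it against an independent direct-integration oracle (exact enumeration
of the 768 discrete covariate cells crossed with Gauss–Hermite
quadrature for age and BMI).

What the generator does *not* emulate: covariate correlations (the
source reports only marginals; menopause is drawn independently of age,
where a real cohort would couple them), follow-up time and censoring
(the endpoint is the binary five-year indicator), and any
treatment-regimen variables.  Passing recovery tests therefore show that
the estimators recover known truths under the stated data-generating
law, not that the synthetic cohort reproduces the real cohort's joint
distribution.

A single integer seed drives everything, split deterministically into
per-stage streams (covariates, exposure, outcome, Monte-Carlo truth), so
a spec is bit-reproducible and the exposure draw can be held fixed while
the outcome model changes.

### Misspecification scenarios

`misspecification_scenarios()` derives two settings used by the
double-robustness suite.  Both describe one nonlinear world: the
structural outcome model gains a quadratic standardized-age term
(coefficient 0.8) and an exposure-by-age interaction (1.0), neither of
which the main-effects parametric working model contains.  In
**Q-hard** the propensity stays logistic-linear — the exposure model is
correctly specifiable and only the outcome model is wrong, so
G-computation is biased while IPTW is not.  In **g-hard** the
structural propensity additionally gains the quadratic age term
(coefficient 0.3), so the fitted weights err in a direction the outcome
genuinely depends on and IPTW is biased.  The asymmetry in that design
is deliberate: an MLE-fitted logistic propensity is *calibrated* on the
covariates it includes, and combined with Hajek normalization this
leaves IPTW nearly unbiased whenever the outcome is linear in those
covariates — a propensity-only nonlinearity, however strong, either
fails to move IPTW or only does so by destroying positivity.  The
magnitudes were chosen once so the misspecified estimator is materially
biased (double-digit simulation z-scores) while the true propensity
stays inside (0.01, 0.99); they are scenario definitions, not tuning
knobs.

## Descriptive battery

`describe()` reproduces a standard clinical "Table 1".  Continuous
variables are gated per exposure arm by Shapiro–Wilk at
$\alpha = 0.05$ (the gate's grouping and level are our choice; the
source states only the gate): both arms normal gives a t-test — pooled
or Welch according to Levene's homogeneity test at 0.05 — and
mean (SD) display; otherwise Mann–Whitney U and median (IQR).
Categorical variables get a chi-square test, replaced by Fisher's exact
test when any expected cell is below 5.  Raw p-values are
Benjamini–Hochberg adjusted across the battery (FDR 5%).  Percentages
are count/group-n × 100, rounded half-up to two decimals to match the
reference table's formatting (R's own `round()` rounds half to even,
which would disagree on exact halves).  Shapiro–Wilk is undefined above
5000 observations; larger arms are thinned evenly over the *sorted*
values, which keeps the gate deterministic and permutation-invariant.
Hypertension appears in the adjustment set but not in the descriptive
battery, matching the source's table layout.

## Diagnostics and sensitivity analysis

**Positivity / overlap** is summarized by the effective sample size
$\mathrm{ESS} = (\sum w)^2 / \sum w^2$ per exposure arm and its ratio to
the arm size; constant weights give ratio 1, and a low ratio flags
weight concentration.  Estimated propensities are truncated to
$[\delta, 1-\delta]$ with $\delta = 0.025$ (configurable; every
truncation event is counted and logged in the report's provenance
block).  **Balance** is assessed by standardized mean differences for
all twelve design columns before and after weighting, with the pooled
*unweighted* SD $\sqrt{(s_1^2 + s_0^2)/2}$ as denominator in both, so
the before/after numbers are directly comparable; |SMD| < 0.1 is the
conventional adequacy threshold.

**Unmeasured confounding** is probed with a confounding-function
sensitivity analysis.  We use the minimal two-parameter version:
constant-in-$W$ functions $c_1 = E[Y(1) \mid A=1] - E[Y(1) \mid A=0]$
and $c_0 = E[Y(0) \mid A=1] - E[Y(0) \mid A=0]$ on the risk-difference
scale, giving bias-corrected means $\psi_1^c = \hat\psi_1 - c_1
\hat P(A=0)$ and $\psi_0^c = \hat\psi_0 + c_0 \hat P(A=1)$ and a
corrected OR on a grid (default $[-0.05, 0.05]$ per axis, 21×21).  The
$(0,0)$ point reproduces the baseline estimate exactly, and the
corrected OR is monotone decreasing in each of $c_1$ and $c_0$ — that is
the direction the correction formulas imply, and the test suite verifies
it together with exact recovery of a planted hidden confounder's truth
at the grid point matching its true $(c_1, c_0)$.  Richer
parameterizations (covariate-dependent confounding functions) are out of
scope; the two-scalar version is what a contour plot over "presence,
direction and magnitude" of unmeasured confounding requires.

## Numerical choices

* Outcome-model probabilities are clipped to $[10^{-6}, 1-10^{-6}]$
  before the logit-offset fluctuation; propensities are truncated once,
  at prediction time, to $[\delta, 1-\delta]$.
* The fluctuation GLM runs with tolerance $10^{-12}$; non-convergence is
  an error with diagnostics, never a silent skip.
* Super-learner CV predictions are clipped to $[10^{-6}, 1-10^{-6}]$
  inside the loss; k-NN vote shares are Laplace-smoothed,
  $(v + 0.5)/(k+1)$, so a unanimous neighbourhood cannot contribute an
  infinite log-loss.
* Apparent separation in a parametric fit (non-convergence or a
  coefficient beyond ±15 on the logit scale) falls back to a
  ridge-stabilized fit with a warning.
* Fold assignment is stratified on the response (and additionally on
  exposure for the outcome model) by seeded permutation within strata,
  guaranteeing both classes in every training fold.
* Degenerate inputs fail loudly: a subset lacking an exposure arm, a
  counterfactual mean of exactly 0 or 1, an all-failed learner registry,
  and >5% failed bootstrap replicates are all errors naming the cause.

## Problem sizes used by the validation suite

The simulation studies behind the package's validation use sizes chosen
to give informative Monte-Carlo error at desk scale: parameter recovery
runs 100 replicates at $n = 20{,}000$ for the parametric estimators
(tolerance three simulation SEs around the integration-oracle truth) and
8 replicates at $n = 2500$ for TMLE-SL with a three-learner registry;
estimator dispersion is checked across 100 replicates at $n = 3386$, the
reference cohort's size; double robustness uses 150 parametric and
8 TMLE-SL replicates at $n = 2500$ per misspecification scenario (each
estimator's bias is judged against its own three-SE band, so the bands
scale with the replicate counts); and CI calibration runs at the study
size $n = 3386$ — where the rare outcome's asymptotics have set in;
much smaller cohorts genuinely undercover — with $B = 200$ bootstrap
resamples and 60 / 35 / 25 replicates for GC / TMLE / TMLE-SL.  The
full six-learner registry is exercised on the single-cohort analyses;
the replicated studies use reduced registries so that the
cross-validated ensembles remain the object under test while the
studies stay re-runnable.

## Known limitations

* The generator cannot be validated against the real cohort's joint
  covariate distribution (unpublished); only marginals are matched.
* The super learner is not cross-fitted (no CV-TMLE); with
  highly adaptive learners on small cohorts, IC-based intervals can be
  optimistic.  The six base learners here are moderately complex and the
  coverage study shows calibrated intervals at the sizes tested.
* Odds ratio only: risk differences/ratios, time-to-event endpoints and
  longitudinal exposures are out of scope.
* Complete-case ingestion; no imputation.

## A worked example

```{r example, eval = FALSE}
spec <- generator_spec(seed = 2026L)     # calibrated defaults, n = 3386
cohort <- generate_cohort(spec)
true_marginal_effect(spec)$or            # known truth, ~1.9

describe(cohort)                         # Table-1 style battery
estimate_gc(cohort)
estimate_iptw(cohort)
estimate_tmle(cohort, "parametric", seed = 1, B = 1000)
estimate_tmle(cohort, "superlearner", seed = 1)   # 15-fold, 6 learners

bal <- balance_table(cohort, estimate_iptw(cohort)$diagnostics$weights)
sensitivity_contour(cohort, estimate_gc)
```
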