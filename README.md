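# causalor

Causal inference for the marginal odds ratio of a binary exposure on a
binary outcome in observational cohorts — built around the question of
whether co-existing diabetes raises five-year mortality in breast-cancer
patients, but applicable to any cohort with the same shape (binary
outcome `Y`, binary exposure `A`, a modest clinical covariate vector
`W`).

## What it computes

The estimand is the marginal odds ratio contrasting mean potential
outcomes,

    OR = E[Y(1)] {1 - E[Y(0)]} / ( {1 - E[Y(1)]} E[Y(0)] ),

estimated four ways:

| method  | nuisance models | consistency requires | 95% CI |
|---------|-----------------|----------------------|--------|
| `estimate_gc`   | outcome regression Q(A,W) | Q correct | percentile bootstrap |
| `estimate_iptw` | propensity g(W), Hajek weighting | g correct | percentile bootstrap |
| `estimate_tmle(..., "parametric")` | both, plus targeted fluctuation | Q **or** g correct | percentile bootstrap |
| `estimate_tmle(..., "superlearner")` | 15-fold cross-validated super learner for both | Q or g correct | efficient influence curve |

The super learner stacks six base learners (random forest, k-nearest
neighbours, RBF-kernel SVM, elastic net, two gradient-boosting
configurations) with convex weights minimizing cross-validated log
loss.  Around the estimators the package provides: a Table-1 style
descriptive battery with a Shapiro-Wilk normality gate and
Benjamini-Hochberg correction (`describe`), sensitivity subsets
(`filter_subset`: drop stage III, drop age >= 70), positivity and
balance diagnostics (`effective_sample_size`, `balance_table`), a
confounding-function contour for unmeasured confounding
(`sensitivity_contour`), and a calibrated synthetic cohort generator
with a known-truth oracle (`generator_spec`, `generate_cohort`,
`true_marginal_effect`) standing in for the undeposited clinical
cohort.  `run_analysis` orchestrates everything from one config, and
`inst/cli/causalor` exposes the pipeline as a command-line tool
(`simulate`, `truth`, `describe`, `run`, `sensitivity`).

See `vignettes/marginal-odds-ratio-methods.Rmd` for the model, the
assumptions, and every numerical design choice.

## A worked example

```r
library(causalor)

spec   <- generator_spec(seed = 2026L)  # calibrated defaults, n = 3386
cohort <- generate_cohort(spec)
true_marginal_effect(spec)
#> <synthetic_truth> E[Y(1)] = 0.10584, E[Y(0)] = 0.05864, OR = 1.9001 (MC-SE logOR 1.06e-03)

estimate_gc(cohort)
#> <estimate_result> GC: OR = 2.0352  (E[Y(1)] = 0.11587, E[Y(0)] = 0.06050, n = 3386)

tmle <- estimate_tmle(cohort, "parametric", seed = 1, B = 400)
tmle
#> <estimate_result> TMLE: OR = 2.0154  (E[Y(1)] = 0.11487, E[Y(0)] = 0.06050, n = 3386)
#>   95% CI [1.3566, 2.8530] (bootstrap)
```

`E[Y(1)]` and `E[Y(0)]` are the estimated mean five-year mortality had
everyone, versus no one, been exposed; the OR contrasts those two
population risks (here the estimators sit near the generator's known
truth of 1.9, with the bootstrap interval reflecting the rarity of
exposed deaths at this sample size).  On the IPTW side,
`balance_table(cohort, estimate_iptw(cohort)$diagnostics$weights)`
shows all post-weighting standardized mean differences below 0.1
(largest 0.076 on this cohort) and effective-sample-size ratios of 0.82
(exposed) and 1.00 (unexposed) — adequate overlap.

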