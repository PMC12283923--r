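swap_exposure <- function(cohort) {
  df <- as.data.frame(cohort)
  df$A <- 1 - df$A
  suppressWarnings(cohort_table(df))
}

test_that("marginal_or implements the estimand map", {
  expect_equal(marginal_or(0.5, 0.5), 1)
  # crude rates from printed 2x2 counts (34/300 exposed, 181/3086
  # unexposed); hand arithmetic: (34 * 2905) / (266 * 181)
  expect_equal(marginal_or(34 / 300, 181 / 3086), 98770 / 48146,
               tolerance = 1e-12)
  expect_equal(marginal_or(34 / 300, 181 / 3086),
               oracle_or(34 / 300, 181 / 3086), tolerance = 1e-14)
  expect_equal(marginal_or(plogis(qlogis(0.05) + log(2)), 0.05), 2,
               tolerance = 1e-12)
  expect_error(marginal_or(0, 0.5), "degenerate.*Y\\(1\\)")
  expect_error(marginal_or(0.5, 1), "degenerate.*Y\\(0\\)")
})

test_that("GC with a saturated fit equals brute-force standardization", {
  co <- discrete_toy()
  fit <- suppressWarnings(
    fit_parametric("outcome", co, formula = .y ~ A * Ki67))
  res <- suppressWarnings(estimate_gc(co, fit))
  expect_equal(res$psi1, oracle_standardize(co$Y, co$A, co["Ki67"], 1),
               tolerance = 1e-10)
  expect_equal(res$psi0, oracle_standardize(co$Y, co$A, co["Ki67"], 0),
               tolerance = 1e-10)
  expect_equal(res$method, "GC")
})

test_that("GC finds a null effect when the outcome ignores exposure", {
  spec <- generator_spec(n = 8000,
                         outcome = replace(default_outcome_coefs(),
                                           "exposure", 0),
                         seed = 61L)
  co <- generate_cohort(spec)
  # three large-sample SEs of the log OR at this n and event rate
  expect_lt(abs(log(estimate_gc(co)$or)), 0.5)
})

test_that("IPTW reduces to arm means under a constant propensity", {
  co <- reference_counts_cohort()
  const_g <- suppressWarnings(
    fit_parametric("propensity", co, formula = .y ~ 1))
  res <- suppressWarnings(estimate_iptw(co, const_g))
  expect_equal(res$psi1, 34 / 300, tolerance = 1e-12)
  expect_equal(res$psi0, 181 / 3086, tolerance = 1e-12)
  expect_equal(res$or, oracle_or(34 / 300, 181 / 3086), tolerance = 1e-12)
})

test_that("IPTW matches the Hajek closed form computed from its propensities", {
  co <- toy_cohort(200, seed = 62)
  gfit <- fit_parametric("propensity", co)
  res <- estimate_iptw(co, gfit)
  g <- truncate_propensity(predict_nuisance(gfit, co), 0.025)
  ora <- oracle_hajek(co$Y, co$A, as.numeric(g))
  expect_equal(res$psi1, ora$psi1, tolerance = 1e-12)
  expect_equal(res$psi0, ora$psi0, tolerance = 1e-12)
  expect_true(all(res$diagnostics$weights >= 1))
})

test_that("TMLE with saturated nuisances leaves the fit untouched (epsilon = 0) and equals GC", {
  co <- discrete_toy()
  qfit <- suppressWarnings(
    fit_parametric("outcome", co, formula = .y ~ A * Ki67))
  gfit <- suppressWarnings(
    fit_parametric("propensity", co, formula = .y ~ Ki67))
  up <- suppressWarnings(tmle_update(co, qfit, gfit, delta = 1e-6))
  expect_lt(max(abs(up$epsilon)), 1e-7)
  gc_res <- suppressWarnings(estimate_gc(co, qfit))
  expect_equal(up$psi1, gc_res$psi1, tolerance = 1e-10)
  expect_equal(up$psi0, gc_res$psi0, tolerance = 1e-10)
  expect_equal(up$psi1, oracle_standardize(co$Y, co$A, co["Ki67"], 1),
               tolerance = 1e-10)
  expect_true(targeting_ok(up))
})

test_that("the targeting property holds after fluctuation on generated cohorts", {
  for (s in c(71L, 72L)) {
    co <- generate_cohort(generator_spec(n = 1500, seed = s))
    up <- tmle_update(co, fit_parametric("outcome", co),
                      fit_parametric("propensity", co))
    expect_lte(abs(mean(up$eic1)), 1e-8 * sd(up$eic1))
    expect_lte(abs(mean(up$eic0)), 1e-8 * sd(up$eic0))
  }
})

test_that("swapping exposure labels inverts the odds ratio", {
  co <- generate_cohort(generator_spec(n = 2500, seed = 63L))
  sw <- swap_exposure(co)
  expect_equal(estimate_gc(sw)$or, 1 / estimate_gc(co)$or,
               tolerance = 1e-8)
  expect_equal(estimate_iptw(sw)$or, 1 / estimate_iptw(co)$or,
               tolerance = 1e-8)
  or1 <- estimate_tmle(co, "parametric", ci = "none")$or
  or2 <- estimate_tmle(sw, "parametric", ci = "none")$or
  expect_equal(or2, 1 / or1, tolerance = 1e-8)
})

test_that("estimators are invariant to row permutation", {
  co <- generate_cohort(generator_spec(n = 1200, seed = 64L))
  set.seed(9)
  perm <- cohort_table(as.data.frame(co)[sample(nrow(co)), ])
  expect_equal(estimate_gc(perm)$or, estimate_gc(co)$or, tolerance = 1e-10)
  expect_equal(estimate_iptw(perm)$or, estimate_iptw(co)$or,
               tolerance = 1e-10)
  expect_equal(estimate_tmle(perm, "parametric", ci = "none")$or,
               estimate_tmle(co, "parametric", ci = "none")$or,
               tolerance = 1e-10)
})

test_that("bootstrap CIs are deterministic given the seed and honour the contract", {
  co <- generate_cohort(generator_spec(n = 900, seed = 65L))
  ci1 <- ci_bootstrap(co, estimate_gc, B = 200, seed = 17)
  ci2 <- ci_bootstrap(co, estimate_gc, B = 200, seed = 17)
  expect_identical(ci1$replicates, ci2$replicates)
  expect_lte(ci1$lower, ci1$upper)
  expect_equal(ci1$construction, "bootstrap")
  expect_error(ci_bootstrap(co, estimate_gc, B = 100, seed = 1), "B >= 200")

  # degenerate constant estimator collapses to a zero-width interval
  const <- function(cohort) list(or = 1.7)
  ci3 <- ci_bootstrap(co, const, B = 200, seed = 1)
  expect_equal(ci3$lower, 1.7)
  expect_equal(ci3$upper, 1.7)
})

test_that("excessive bootstrap failures raise an actionable error", {
  co <- generate_cohort(generator_spec(n = 300, seed = 66L))
  flaky <- local({
    k <- 0
    function(cohort) {
      k <<- k + 1
      if (k %% 2 == 0) stop("fail") else list(or = 2)
    }
  })
  expect_error(ci_bootstrap(co, flaky, B = 200, seed = 1),
               "replicates failed")
})

test_that("influence-curve CI collapses under pointwise cancellation and matches bootstrap width at scale", {
  fake <- list(psi1 = 0.3, psi0 = 0.3, eic1 = rnorm(100), n = 100)
  fake$eic0 <- fake$eic1
  ci <- ci_influence_curve(fake)
  expect_equal(ci$lower, 1, tolerance = 1e-12)
  expect_equal(ci$upper, 1, tolerance = 1e-12)

  # large-sample equivalence of the two constructions (well-specified model)
  co <- generate_cohort(generator_spec(n = 5000, seed = 67L))
  up <- tmle_update(co, fit_parametric("outcome", co),
                    fit_parametric("propensity", co))
  ic <- ci_influence_curve(up)
  bs <- ci_bootstrap(co, function(c) estimate_tmle(c, "parametric",
                                                   ci = "none"),
                     B = 300, seed = 5)
  w_ic <- log(ic$upper) - log(ic$lower)
  w_bs <- log(bs$upper) - log(bs$lower)
  expect_lt(abs(w_ic - w_bs) / w_bs, 0.2)
})

test_that("estimate_tmle composes nuisances, CI and method tags", {
  co <- generate_cohort(generator_spec(n = 700, seed = 68L))
  par <- estimate_tmle(co, "parametric", seed = 2, ci = "bootstrap", B = 200)
  expect_equal(par$method, "TMLE")
  expect_equal(par$ci$construction, "bootstrap")
  expect_named(par$epsilon, c("H1", "H0"))

  reg <- default_learner_registry()[c("elastic_net", "xgb_shallow")]
  sl <- estimate_tmle(co, "superlearner", seed = 2, registry = reg)
  expect_equal(sl$method, "TMLE_SL")
  expect_equal(sl$ci$construction, "influence_curve")
  expect_true(sl$ci$lower <= sl$or && sl$or <= sl$ci$upper)
  expect_lte(abs(sl$diagnostics$mean_eic1), 1e-8 * sl$diagnostics$sd_eic1)
})

test_that("estimate results serialize to forest-plot TSV and JSON", {
  co <- generate_cohort(generator_spec(n = 600, seed = 69L))
  res <- list(estimate_gc(co), estimate_iptw(co))
  res[[1]]$ci <- list(lower = 1, upper = 3, level = 0.95,
                      construction = "bootstrap")
  tsv <- tempfile(fileext = ".tsv")
  write_estimates(res, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$method, c("GC", "IPTW"))
  expect_equal(back$or, vapply(res, `[[`, 0, "or"), tolerance = 1e-10)
})
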