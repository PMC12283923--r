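fast_registry <- function() {
  default_learner_registry()[c("elastic_net", "knn", "xgb_shallow")]
}

test_that("parametric fit recovers a pure-noise response", {
  set.seed(21)
  n <- 4000
  co <- generate_cohort(generator_spec(n = n, seed = 21L))
  co$Y <- rbinom(n, 1, 0.5)  # outcome independent of everything
  fit <- fit_parametric("outcome", co)
  p <- predict_nuisance(fit, co)
  expect_lt(abs(mean(p) - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(sd(p), 0.03)
})

test_that("saturated parametric fits reproduce empirical stratum means", {
  co <- discrete_toy()
  fit <- suppressWarnings(
    fit_parametric("outcome", co, formula = .y ~ A * Ki67))
  for (a in c(0, 1)) {
    pred <- suppressWarnings(predict_counterfactual(fit, co, a))
    for (w in c(0, 1)) {
      emp <- mean(co$Y[co$A == a & co$Ki67 == w])
      expect_equal(unique(round(pred[co$Ki67 == w], 10)), round(emp, 10))
    }
  }
  # zero exposure coefficient ensures identical counterfactual predictions
  fit0 <- suppressWarnings(fit_parametric("outcome", co, formula = .y ~ Ki67))
  expect_equal(suppressWarnings(predict_counterfactual(fit0, co, 0)),
               suppressWarnings(predict_counterfactual(fit0, co, 1)))
})

test_that("propensity fit on a null-propensity spec is near-constant at the intercept", {
  spec <- generator_spec(n = 20000,
                         propensity = c("(Intercept)" = qlogis(0.0886)),
                         seed = 8L)
  co <- generate_cohort(spec)
  fit <- fit_parametric("propensity", co)
  p <- predict_nuisance(fit, co)
  expect_lt(abs(mean(p) - 0.0886), 3 * sqrt(0.0886 * 0.9114 / 20000))
  expect_lt(sd(p), 0.02)
})

test_that("counterfactual prediction enforces its contract", {
  co <- toy_cohort(80, seed = 4)
  qfit <- fit_parametric("outcome", co)
  gfit <- fit_parametric("propensity", co)
  expect_error(predict_counterfactual(gfit, co, 1), "outcome-role")
  expect_error(predict_counterfactual(qfit, co, 2), "0 or 1")
  for (a in c(0, 1)) {
    p <- predict_counterfactual(qfit, co, a)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("separation triggers the ridge-stabilized fallback", {
  co <- make_cohort(Y = rep(c(1, 0), each = 20), A = rep(c(1, 0), each = 20),
                    Ki67 = rbinom(40, 1, 0.5), age = rnorm(40, 50, 5))
  w <- capture_warnings(fit <- fit_parametric("outcome", co))
  expect_match(w, "separation", all = FALSE)
  expect_equal(fit$kind, "parametric_ridge")
  p <- suppressWarnings(predict_nuisance(fit, co))
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
})

test_that("a singleton registry collapses the super learner to that learner", {
  co <- generate_cohort(generator_spec(n = 400, seed = 41L))
  reg <- default_learner_registry()["elastic_net"]
  sl <- fit_superlearner("propensity", co, folds = 15, seed = 2,
                         registry = reg)
  expect_equal(unname(sl$weights), 1)
  single <- reg$elastic_net$fit(encode_design(co), co$A,
                                seed = causalor:::seed_offset(2, 9001L))
  expect_equal(predict_nuisance(sl, co),
               causalor:::clip_prob(reg$elastic_net$predict(
                 single, encode_design(co))),
               tolerance = 1e-10)
})

test_that("duplicated learners leave the ensemble prediction unchanged", {
  co <- generate_cohort(generator_spec(n = 400, seed = 42L))
  en <- default_learner_registry()["elastic_net"]
  dup <- list(en1 = en$elastic_net, en2 = en$elastic_net)
  sl1 <- fit_superlearner("propensity", co, folds = 15, seed = 3,
                          registry = en)
  sl2 <- fit_superlearner("propensity", co, folds = 15, seed = 3,
                          registry = dup)
  expect_equal(sum(sl2$weights), 1, tolerance = 1e-9)
  expect_equal(predict_nuisance(sl2, co), predict_nuisance(sl1, co),
               tolerance = 1e-8)
})

test_that("super-learner weights live on the simplex and beat every single learner", {
  co <- generate_cohort(generator_spec(n = 600, seed = 43L))
  for (role in c("propensity", "outcome")) {
    sl <- fit_superlearner(role, co, folds = 15, seed = 4,
                           registry = fast_registry())
    expect_true(all(sl$weights >= 0))
    expect_equal(sum(sl$weights), 1, tolerance = 1e-9)
    expect_lte(sl$ensemble_cv_risk, min(sl$cv_risks) + 1e-8)
    expect_lte(sl$ensemble_cv_risk, max(sl$cv_risks))
    p <- predict_nuisance(sl, co)
    expect_true(all(p >= 1e-6 & p <= 1 - 1e-6))
  }
})

test_that("the full six-learner registry trains and stratified folds keep both classes", {
  co <- generate_cohort(generator_spec(n = 300, seed = 44L))
  sl <- suppressWarnings(fit_superlearner("outcome", co, folds = 15, seed = 5))
  expect_length(sl$weights, 6L)
  expect_equal(sum(sl$weights), 1, tolerance = 1e-9)
  for (v in seq_len(15L)) {
    expect_gte(length(unique(co$Y[sl$fold_id != v])), 2L)
  }
  expect_equal(sort(unique(sl$fold_id)), 1:15)
})

test_that("a failing learner is dropped with a warning, weights renormalized", {
  co <- generate_cohort(generator_spec(n = 300, seed = 45L))
  broken <- causalor:::make_learner("broken",
    fit = function(X, y, seed) stop("boom"),
    predict = function(m, X) rep(0.5, nrow(X)))
  reg <- c(default_learner_registry()["elastic_net"], list(broken = broken))
  expect_warning(sl <- fit_superlearner("propensity", co, folds = 15,
                                        seed = 6, registry = reg),
                 "'broken' failed.*dropped")
  expect_equal(sl$dropped, "broken")
  expect_equal(sum(sl$weights), 1, tolerance = 1e-9)
  reg_all_bad <- list(broken = broken)
  expect_error(suppressWarnings(
    fit_superlearner("propensity", co, folds = 15, seed = 6,
                     registry = reg_all_bad)), "all super-learner")
})

test_that("propensity truncation clamps and counts exactly once", {
  g <- c(0.001, 0.5, 0.999, 0.025, 0.975)
  tg <- truncate_propensity(g, delta = 0.025)
  expect_equal(as.numeric(tg), c(0.025, 0.5, 0.975, 0.025, 0.975))
  expect_equal(attr(tg, "n_truncated"), 2L)
})

test_that("super-learner fits serialize an audit record", {
  co <- generate_cohort(generator_spec(n = 400, seed = 46L))
  sl <- fit_superlearner("propensity", co, folds = 15, seed = 7,
                         registry = fast_registry())
  path <- tempfile(fileext = ".json")
  write_superlearner_audit(sl, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$weights), sl$weights, tolerance = 1e-12)
  expect_equal(back$folds, 15L)
  expect_error(write_superlearner_audit(fit_parametric("outcome", co), path),
               "super-learner")
})
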