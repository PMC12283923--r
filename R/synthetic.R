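# Synthetic cohort generator with known structural equations, so every
# estimator is testable by parameter recovery against an exact truth.

expit <- plogis

seed_offset <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

#' Specify a synthetic cohort generator
#'
#' Structural equations: covariates W are drawn from the stated marginals
#' (independent by default), exposure `A ~ Bernoulli(expit(gamma'(1, W)))`
#' and outcome `Y ~ Bernoulli(expit(beta'(1, A, W)))`.  Coefficient vectors are
#' named over the design columns of [encode_design()]; three extra names are
#' recognised for nonlinear terms used by the misspecification scenarios:
#' `age_std_sq` (square of standardized age) in either model and
#' `exposure_age_std` (exposure x standardized age) in the outcome model.
#'
#' @param n cohort size.
#' @param age_mean,age_sd,bmi_mean,bmi_sd normal marginals for the two
#'   continuous covariates.
#' @param binary_rates named Bernoulli rates for the eight binary covariates.
#' @param stage_probs probabilities of stage I/II/III (must sum to 1).
#' @param propensity named coefficients (logit scale) incl. `(Intercept)`.
#' @param outcome named coefficients (logit scale) incl. `(Intercept)` and
#'   `exposure`.
#' @param seed integer master seed, split deterministically into per-stage
#'   streams (covariates / exposure / outcome / Monte-Carlo truth).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n = 3386,
                           age_mean = 51, age_sd = 10.4,
                           bmi_mean = 23.9, bmi_sd = 3.3,
                           binary_rates = c(
                             Ki67 = 0.4108, P53 = 0.3860, HER2 = 0.7404,
                             ER = 0.7262, PR = 0.6367,
                             lymphatic_metastasis = 0.6878,
                             hypertension = 0.25, menopause = 0.4631),
                           stage_probs = c(I = 0.4533, II = 0.4064,
                                           III = 0.1403),
                           propensity = default_propensity_coefs(),
                           outcome = default_outcome_coefs(),
                           seed = 20260101L) {
  fl <- cohort_fields()
  stopifnot(n >= 2, age_sd > 0, bmi_sd > 0)
  if (!all(fl$binary %in% names(binary_rates))) {
    stop("binary_rates must name all eight binary covariates", call. = FALSE)
  }
  if (any(binary_rates <= 0 | binary_rates >= 1)) {
    stop("all Bernoulli rates must lie in (0, 1)", call. = FALSE)
  }
  if (abs(sum(stage_probs) - 1) > 1e-8) {
    stop("stage probabilities must sum to 1", call. = FALSE)
  }
  if (!"(Intercept)" %in% names(propensity) ||
      !all(c("(Intercept)", "exposure") %in% names(outcome))) {
    stop("coefficient vectors need '(Intercept)' (and 'exposure' for the outcome model)",
         call. = FALSE)
  }
  structure(list(n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 binary_rates = binary_rates[fl$binary],
                 stage_probs = stage_probs,
                 propensity = propensity, outcome = outcome,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Default structural coefficients of the synthetic generator
#'
#' Confounding runs through age, BMI, hypertension and stage (all raise
#' both diabetes risk and mortality).  Intercepts and the exposure effect
#' are calibrated by Monte-Carlo root-solving so the generated marginals
#' track the reference cohort: exposure prevalence 8.86%, 5-year mortality
#' 6.35%, true marginal OR approximately 1.9.
#'
#' @return Named coefficient vector on the logit scale; see
#'   [generator_spec()] for the recognised names.
#' @export
default_propensity_coefs <- function() {
  c("(Intercept)" = -6.674034,
    age = 0.04, BMI = 0.08, hypertension = 0.80,
    stage_II = 0.05, stage_III = 0.15)
}

#' @rdname default_propensity_coefs
#' @export
default_outcome_coefs <- function() {
  c("(Intercept)" = -5.999989, exposure = 0.669576,
    age = 0.03, BMI = 0.03,
    Ki67 = 0.30, P53 = 0.25, HER2 = 0.10, ER = -0.30, PR = -0.30,
    lymphatic_metastasis = 0.50, hypertension = 0.20, menopause = 0.10,
    stage_II = 0.60, stage_III = 1.40)
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> n = %d, seed = %d\n", x$n, x$seed))
  cat("  exposure coefficient (log odds):",
      format(x$outcome[["exposure"]]), "\n")
  invisible(x)
}

# covariate draw shared by generate() and the truth oracle; continuous
# marginals are normals clamped to clinically plausible ranges (age 25-85,
# BMI 15-40), which also bounds the true propensity away from 0 and 1
draw_covariates <- function(spec, n) {
  fl <- cohort_fields()
  W <- data.frame(
    age = pmin(pmax(rnorm(n, spec$age_mean, spec$age_sd), 25), 85),
    BMI = pmin(pmax(rnorm(n, spec$bmi_mean, spec$bmi_sd), 15), 40)
  )
  for (v in fl$binary) W[[v]] <- rbinom(n, 1L, spec$binary_rates[[v]])
  W$stage <- sample(stage_levels(), n, replace = TRUE,
                    prob = spec$stage_probs)
  W
}

design_from_W <- function(W) {
  fl <- cohort_fields()
  X <- cbind(as.matrix(W[, c(fl$continuous, fl$binary)]),
             stage_II = as.numeric(W$stage == "II"),
             stage_III = as.numeric(W$stage == "III"))
  storage.mode(X) <- "double"
  X
}

linpred <- function(coefs, X, spec, a = NULL) {
  lp <- rep(coefs[["(Intercept)"]], nrow(X))
  lin <- intersect(names(coefs), colnames(X))
  if (length(lin) > 0L) lp <- lp + drop(X[, lin, drop = FALSE] %*% coefs[lin])
  z <- (X[, "age"] - spec$age_mean) / spec$age_sd
  if ("age_std_sq" %in% names(coefs)) lp <- lp + coefs[["age_std_sq"]] * z^2
  if (!is.null(a)) {
    lp <- lp + coefs[["exposure"]] * a
    if ("exposure_age_std" %in% names(coefs)) {
      lp <- lp + coefs[["exposure_age_std"]] * a * z
    }
  }
  lp
}

propensity_true <- function(spec, W) {
  expit(linpred(spec$propensity, design_from_W(W), spec))
}

outcome_prob_true <- function(spec, W, a) {
  expit(linpred(spec$outcome, design_from_W(W), spec, a = a))
}

#' Generate a synthetic cohort
#'
#' Draws covariates, exposure and outcome from the spec's structural
#' equations; bit-reproducible from `spec$seed`.  If the empirical
#' propensity range leaves (0.01, 0.99) a positivity warning is attached
#' to the cohort (attribute `positivity_warning`).
#'
#' @param spec a [generator_spec()].
#' @return A `cohort_table` of `spec$n` patients.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed_offset(spec$seed, 1L)); W <- draw_covariates(spec, spec$n)
  g <- propensity_true(spec, W)
  set.seed(seed_offset(spec$seed, 2L)); A <- rbinom(spec$n, 1L, g)
  q <- outcome_prob_true(spec, W, A)
  set.seed(seed_offset(spec$seed, 3L)); Y <- rbinom(spec$n, 1L, q)
  cohort <- cohort_table(cbind(data.frame(Y = Y, A = A), W))
  if (min(g) < 0.01 || max(g) > 0.99) {
    warning("positivity: true propensity outside (0.01, 0.99) for some patients",
            call. = FALSE)
    attr(cohort, "positivity_warning") <- TRUE
  }
  cohort
}

#' Monte-Carlo truth for a generator spec
#'
#' Computes the true mean potential outcomes `E[Y(1)]` and `E[Y(0)]` by
#' averaging the structural outcome probabilities over a large covariate
#' sample, and the true marginal odds ratio
#' `OR = E[Y(1)] (1 - E[Y(0)]) / ((1 - E[Y(1)]) E[Y(0)])`.
#'
#' @param spec a [generator_spec()].
#' @param mc_n Monte-Carlo sample size (>= 1e5).
#' @return A `synthetic_truth` list: `psi1`, `psi0`, `or`, Monte-Carlo
#'   standard errors `mc_se_psi1`, `mc_se_psi0`, `mc_se_log_or`, `mc_n`,
#'   `seed`.
#' @export
true_marginal_effect <- function(spec, mc_n = 1e6) {
  stopifnot(inherits(spec, "generator_spec"), mc_n >= 1e5)
  set.seed(seed_offset(spec$seed, 9L))
  W <- draw_covariates(spec, mc_n)
  p1 <- outcome_prob_true(spec, W, 1)
  p0 <- outcome_prob_true(spec, W, 0)
  psi1 <- mean(p1); psi0 <- mean(p0)
  se1 <- sd(p1) / sqrt(mc_n); se0 <- sd(p0) / sqrt(mc_n)
  se_log_or <- sqrt(se1^2 / (psi1 * (1 - psi1))^2 +
                    se0^2 / (psi0 * (1 - psi0))^2)
  structure(list(psi1 = psi1, psi0 = psi0,
                 or = marginal_or(psi1, psi0),
                 mc_se_psi1 = se1, mc_se_psi0 = se0,
                 mc_se_log_or = se_log_or,
                 mc_n = mc_n, seed = spec$seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> E[Y(1)] = %.5f, E[Y(0)] = %.5f, OR = %.4f (MC-SE logOR %.2e)\n",
              x$psi1, x$psi0, x$or, x$mc_se_log_or))
  invisible(x)
}

#' Misspecification scenarios for double-robustness checks
#'
#' Both scenarios describe one nonlinear world: the structural outcome
#' model gains a quadratic standardized-age term and an exposure x age
#' interaction, neither of which the main-effects parametric working
#' model contains.  In `q_hard` the propensity stays logistic-linear, so
#' the exposure model is correctly specifiable and only the outcome
#' model is wrong.  In `g_hard` the structural propensity additionally
#' gains the quadratic age term, so the fitted weights err exactly in a
#' direction the outcome depends on.  (With an outcome linear in the
#' fitted covariates, a misspecified-but-calibrated logistic propensity
#' leaves Hajek IPTW nearly unbiased, which is why the propensity
#' nonlinearity alone is not enough to break IPTW.)  `correct` is the
#' unmodified spec.
#'
#' @param spec a [generator_spec()].
#' @return Named list of `generator_spec`s: `correct`, `q_hard`, `g_hard`.
#' @export
misspecification_scenarios <- function(spec) {
  q_hard <- spec
  q_hard$outcome <- c(spec$outcome,
                      age_std_sq = 0.8, exposure_age_std = 1.0)
  g_hard <- q_hard
  g_hard$propensity <- c(spec$propensity, age_std_sq = 0.3)
  list(correct = spec, q_hard = q_hard, g_hard = g_hard)
}

# spec I/O ---------------------------------------------------------------

#' Read / write a generator spec (YAML or JSON)
#'
#' @param path file path; `.json` selects JSON, otherwise YAML.
#' @return [generator_spec()] for the reader; `path` for the writer.
#' @export
read_generator_spec <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  generator_spec(
    n = raw$n %||% 3386,
    age_mean = raw$age_mean %||% 51, age_sd = raw$age_sd %||% 10.4,
    bmi_mean = raw$bmi_mean %||% 23.9, bmi_sd = raw$bmi_sd %||% 3.3,
    binary_rates = unlist(raw$binary_rates %||%
                            as.list(generator_spec()$binary_rates)),
    stage_probs = unlist(raw$stage_probs %||%
                           as.list(generator_spec()$stage_probs)),
    propensity = unlist(raw$propensity %||%
                          as.list(default_propensity_coefs())),
    outcome = unlist(raw$outcome %||% as.list(default_outcome_coefs())),
    seed = raw$seed %||% 20260101L
  )
}

#' @rdname read_generator_spec
#' @param spec a [generator_spec()].
#' @export
write_generator_spec <- function(spec, path) {
  payload <- list(n = spec$n, age_mean = spec$age_mean, age_sd = spec$age_sd,
                  bmi_mean = spec$bmi_mean, bmi_sd = spec$bmi_sd,
                  binary_rates = as.list(spec$binary_rates),
                  stage_probs = as.list(spec$stage_probs),
                  propensity = as.list(spec$propensity),
                  outcome = as.list(spec$outcome), seed = spec$seed)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
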