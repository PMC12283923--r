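# Four marginal odds-ratio estimators (G-computation, IPTW, TMLE,
# TMLE + super learner) and their confidence intervals.

#' Marginal odds ratio from two counterfactual means
#'
#' `OR = psi1 (1 - psi0) / ((1 - psi1) psi0)`, the odds ratio contrasting
#' the mean potential outcomes `E[Y(1)]` and `E[Y(0)]`.
#'
#' @param psi1,psi0 counterfactual means, strictly inside (0, 1).
#' @return The marginal odds ratio.
#' @export
marginal_or <- function(psi1, psi0) {
  if (psi1 <= 0 || psi1 >= 1) {
    stop("degenerate counterfactual mean E[Y(1)] = ", psi1, call. = FALSE)
  }
  if (psi0 <= 0 || psi0 >= 1) {
    stop("degenerate counterfactual mean E[Y(0)] = ", psi0, call. = FALSE)
  }
  (psi1 * (1 - psi0)) / ((1 - psi1) * psi0)
}

new_estimate_result <- function(method, psi1, psi0, n, covariates,
                                ci = NULL, epsilon = NULL, boot = NULL,
                                diagnostics = NULL) {
  structure(list(method = method, psi1 = psi1, psi0 = psi0,
                 or = marginal_or(psi1, psi0), ci = ci, n = n,
                 covariates = covariates, epsilon = epsilon, boot = boot,
                 diagnostics = diagnostics),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("<estimate_result> %s: OR = %.4f  (E[Y(1)] = %.5f, E[Y(0)] = %.5f, n = %d)\n",
              x$method, x$or, x$psi1, x$psi0, x$n))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI [%.4f, %.4f] (%s)\n",
                x$ci$lower, x$ci$upper, x$ci$construction))
  }
  invisible(x)
}

design_cols <- function() {
  c("age", "BMI", cohort_fields()$binary, "stage_II", "stage_III")
}

# G-computation ----------------------------------------------------------

#' G-computation (standardization) estimate of the marginal odds ratio
#'
#' Averages counterfactual outcome-model predictions over the empirical
#' covariate distribution: `psi_a = mean_i Q-hat(a, W_i)`.
#'
#' @param cohort a `cohort_table`.
#' @param outcome_fit an outcome-role `nuisance_fit`; a main-effects
#'   parametric fit on `cohort` when `NULL`.
#' @return An `estimate_result` (method `"GC"`, no CI; see
#'   [ci_bootstrap()]).
#' @export
estimate_gc <- function(cohort, outcome_fit = NULL) {
  check_both_arms(cohort)
  design <- encode_design(cohort, warn_constant = FALSE)
  if (is.null(outcome_fit)) {
    outcome_fit <- fit_parametric("outcome", cohort, design)
  }
  psi1 <- mean(predict_nuisance(outcome_fit, cohort, a = 1, design = design))
  psi0 <- mean(predict_nuisance(outcome_fit, cohort, a = 0, design = design))
  new_estimate_result("GC", psi1, psi0, nrow(cohort), design_cols())
}

# IPTW -------------------------------------------------------------------

#' IPTW (Hajek) estimate of the marginal odds ratio
#'
#' Unstabilized inverse-probability weights
#' `w_i = A_i / g-hat(W_i) + (1 - A_i) / (1 - g-hat(W_i))` with the
#' propensity truncated to `[delta, 1 - delta]`, then Hajek
#' (weight-normalized) arm means.
#'
#' @param cohort a `cohort_table`.
#' @param propensity_fit a propensity-role `nuisance_fit`; parametric fit
#'   when `NULL`.
#' @param delta propensity truncation bound.
#' @return An `estimate_result` (method `"IPTW"`) carrying a weight summary
#'   in `$diagnostics`.
#' @export
estimate_iptw <- function(cohort, propensity_fit = NULL, delta = 0.025) {
  check_both_arms(cohort)
  design <- encode_design(cohort, warn_constant = FALSE)
  if (is.null(propensity_fit)) {
    propensity_fit <- fit_parametric("propensity", cohort, design)
  }
  g <- truncate_propensity(
    predict_nuisance(propensity_fit, cohort, design = design), delta)
  a <- cohort$A; y <- cohort$Y
  w <- a / g + (1 - a) / (1 - g)
  if (sum(w[a == 1]) == 0 || sum(w[a == 0]) == 0) {
    stop("positivity error: an exposure arm has zero total weight",
         call. = FALSE)
  }
  psi1 <- sum(w[a == 1] * y[a == 1]) / sum(w[a == 1])
  psi0 <- sum(w[a == 0] * y[a == 0]) / sum(w[a == 0])
  diag <- list(weights = w, g = as.numeric(g),
               n_truncated = attr(g, "n_truncated"),
               weight_range = range(w))
  new_estimate_result("IPTW", psi1, psi0, nrow(cohort), design_cols(),
                      diagnostics = diag)
}

# TMLE -------------------------------------------------------------------

# 1-D logistic MLE for a no-intercept fluctuation with offset: solves
# sum h (y - expit(off + eps h)) = 0 by safeguarded Newton
fluctuation_mle <- function(h, y, off, g_all, tol = 1e-12, maxit = 100L) {
  eps <- 0
  score <- function(e) sum(h * (y - plogis(off + e * h)))
  s <- score(eps)
  for (it in seq_len(maxit)) {
    mu <- plogis(off + eps * h)
    info <- sum(h^2 * mu * (1 - mu))
    if (info <= 0) break
    step <- s / info
    # step-halving keeps the update inside the region where the score
    # actually decreases in magnitude
    for (k in 1:30) {
      s_new <- score(eps + step)
      if (abs(s_new) <= abs(s) || abs(step) < tol) break
      step <- step / 2
    }
    eps <- eps + step
    s <- s_new
    if (abs(s) < tol * max(1, length(y)) * 1e-4 || abs(step) < tol) {
      return(eps)
    }
  }
  if (abs(s) > 1e-6 * length(y)) {
    stop("TMLE fluctuation did not converge (score = ", signif(s, 4),
         ", epsilon = ", signif(eps, 4),
         "; min g = ", signif(min(g_all), 4), ")", call. = FALSE)
  }
  eps
}

#' Targeted update of the outcome regression
#'
#' Fluctuates the initial outcome fit along the least-favorable submodel:
#' clever covariates `H1_i = A_i / g-hat(W_i)` and
#' `H0_i = (1 - A_i) / (1 - g-hat(W_i))` enter a no-intercept logistic
#' regression of Y with offset `logit Q-hat(A_i, W_i)`, giving
#' `(epsilon1, epsilon0)`; the updated predictions are
#' `Q* (a, W) = expit(logit Q-hat(a, W) + epsilon_a H_a)` with `H_a`
#' evaluated at exposure `a`.  At the fitted `(epsilon1, epsilon0)` the
#' efficient-influence-curve score equation is solved.
#'
#' @param cohort a `cohort_table`.
#' @param outcome_fit outcome-role `nuisance_fit`.
#' @param propensity_fit propensity-role `nuisance_fit`.
#' @param delta propensity truncation bound.
#' @return List with `psi1`, `psi0`, `epsilon`, updated predictions
#'   `Qstar1`, `Qstar0`, `QstarA`, truncated `g`, clever covariates, and
#'   per-patient efficient influence curves `eic1`, `eic0`.
#' @export
tmle_update <- function(cohort, outcome_fit, propensity_fit,
                        delta = 0.025) {
  a <- cohort$A; y <- cohort$Y
  design <- encode_design(cohort, warn_constant = FALSE)
  g <- truncate_propensity(
    predict_nuisance(propensity_fit, cohort, design = design), delta)
  Q1 <- clip_prob(predict_nuisance(outcome_fit, cohort, a = 1,
                                   design = design))
  Q0 <- clip_prob(predict_nuisance(outcome_fit, cohort, a = 0,
                                   design = design))
  QA <- ifelse(a == 1, Q1, Q0)

  H1 <- a / g
  H0 <- (1 - a) / (1 - g)
  # the two score equations decouple exactly (H1 vanishes off the exposed
  # arm and H0 off the unexposed), so each epsilon is a 1-D logistic MLE
  eps <- c(
    H1 = fluctuation_mle(H1[a == 1], y[a == 1], qlogis(QA[a == 1]), g),
    H0 = fluctuation_mle(H0[a == 0], y[a == 0], qlogis(QA[a == 0]), g)
  )

  Qstar1 <- plogis(qlogis(Q1) + eps[["H1"]] / g)
  Qstar0 <- plogis(qlogis(Q0) + eps[["H0"]] / (1 - g))
  QstarA <- ifelse(a == 1, Qstar1, Qstar0)
  psi1 <- mean(Qstar1); psi0 <- mean(Qstar0)

  eic1 <- H1 * (y - QstarA) + Qstar1 - psi1
  eic0 <- H0 * (y - QstarA) + Qstar0 - psi0

  list(psi1 = psi1, psi0 = psi0, epsilon = eps,
       Qstar1 = Qstar1, Qstar0 = Qstar0, QstarA = QstarA,
       g = as.numeric(g), n_truncated = attr(g, "n_truncated"),
       H1 = H1, H0 = H0, eic1 = eic1, eic0 = eic0, n = nrow(cohort))
}

#' TMLE / TMLE-SL estimate of the marginal odds ratio
#'
#' Composes nuisance fitting (parametric logistic models, or the
#' cross-validated super learner for both the outcome and exposure
#' models), the targeted fluctuation of [tmle_update()], and the estimand
#' map [marginal_or()].  The confidence interval is percentile bootstrap
#' for the parametric variant and efficient-influence-curve based for the
#' super-learner variant by default.
#'
#' @param cohort a `cohort_table`.
#' @param nuisance `"parametric"` (method tag `TMLE`) or `"superlearner"`
#'   (method tag `TMLE_SL`).
#' @param seed seed for super-learner folds and the bootstrap.
#' @param folds,registry super-learner settings, see [fit_superlearner()].
#' @param delta propensity truncation bound.
#' @param ci `"auto"` (bootstrap for TMLE, influence-curve for TMLE_SL),
#'   `"bootstrap"`, `"influence_curve"`, or `"none"`.
#' @param B bootstrap replicates when a bootstrap CI is requested.
#' @return An `estimate_result` with `$epsilon` and an EIC diagnostics
#'   block.
#' @export
estimate_tmle <- function(cohort,
                          nuisance = c("parametric", "superlearner"),
                          seed = 1L, folds = 15L,
                          registry = default_learner_registry(),
                          delta = 0.025,
                          ci = c("auto", "bootstrap", "influence_curve",
                                 "none"),
                          B = 1000L) {
  nuisance <- match.arg(nuisance)
  ci <- match.arg(ci)
  check_both_arms(cohort)
  point <- tmle_point(cohort, nuisance, seed, folds, registry, delta)
  method <- if (nuisance == "parametric") "TMLE" else "TMLE_SL"
  res <- new_estimate_result(method, point$psi1, point$psi0, nrow(cohort),
                             design_cols(), epsilon = point$epsilon,
                             diagnostics = list(
                               mean_eic1 = mean(point$eic1),
                               mean_eic0 = mean(point$eic0),
                               sd_eic1 = sd(point$eic1),
                               sd_eic0 = sd(point$eic0),
                               g = point$g,
                               n_truncated = point$n_truncated))
  if (ci == "auto") {
    ci <- if (nuisance == "parametric") "bootstrap" else "influence_curve"
  }
  if (ci == "influence_curve") {
    res$ci <- ci_influence_curve(point)
  } else if (ci == "bootstrap") {
    starts <- if (nuisance == "parametric") point$starts else NULL
    est_fun <- function(boot_cohort) {
      pt <- tmle_point(boot_cohort, nuisance, seed, folds, registry, delta,
                       starts = starts)
      new_estimate_result(method, pt$psi1, pt$psi0, nrow(boot_cohort),
                          design_cols())
    }
    bs <- ci_bootstrap(cohort, est_fun, B = B,
                       seed = seed_offset(seed, 77L))
    res$ci <- bs
    res$boot <- list(B = bs$B, failures = bs$failures)
  }
  res
}

tmle_point <- function(cohort, nuisance, seed, folds, registry, delta,
                       starts = NULL) {
  if (nuisance == "parametric") {
    design <- encode_design(cohort, warn_constant = FALSE)
    qf <- fit_parametric("outcome", cohort, design, start = starts$q)
    gf <- fit_parametric("propensity", cohort, design, start = starts$g)
  } else {
    qf <- fit_superlearner("outcome", cohort, folds = folds,
                           seed = seed_offset(seed, 11L),
                           registry = registry)
    gf <- fit_superlearner("propensity", cohort, folds = folds,
                           seed = seed_offset(seed, 22L),
                           registry = registry)
  }
  tmle_update(cohort, qf, gf, delta = delta)
}

# confidence intervals ---------------------------------------------------

#' Nonparametric bootstrap percentile confidence interval
#'
#' Resamples patients with replacement and re-runs the full estimation
#' pipeline (including nuisance refits) on each replicate; the CI is the
#' 2.5/97.5 percentile interval of the replicate odds ratios.  Replicates
#' failing (separation, an empty exposure arm) are dropped and counted; an
#' error is raised if more than 5% fail.
#'
#' @param cohort a `cohort_table`.
#' @param estimator function `cohort -> estimate_result`.
#' @param B number of replicates (>= 200).
#' @param seed RNG seed; the same seed reproduces the interval exactly.
#' @param level confidence level.
#' @return List `lower`, `upper`, `level`, `construction = "bootstrap"`,
#'   `B`, `failures`, `replicates`.
#' @export
ci_bootstrap <- function(cohort, estimator, B = 1000L, seed = 1L,
                         level = 0.95) {
  if (B < 200L) stop("bootstrap requires B >= 200", call. = FALSE)
  n <- nrow(cohort)
  df <- as.data.frame(cohort)
  set.seed(seed)
  ors <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- structure(df[idx, , drop = FALSE], n_dropped = 0L,
                      class = c("cohort_table", "data.frame"))
    ors[b] <- tryCatch(suppressWarnings(estimator(boot)$or),
                       error = function(e) NA_real_)
  }
  failures <- sum(is.na(ors))
  if (failures > 0.05 * B) {
    stop(sprintf(
      "%d of %d bootstrap replicates failed; consider a larger cohort or a wider truncation bound",
      failures, B), call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- quantile(ors, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(lower = qs[1L], upper = qs[2L], level = level,
       construction = "bootstrap", B = B, failures = failures,
       replicates = ors)
}

#' Efficient-influence-curve confidence interval for the TMLE odds ratio
#'
#' Maps the per-arm influence curves to the influence curve of the log
#' odds ratio by the delta method,
#' `D_logOR = D1 / (psi1 (1 - psi1)) - D0 / (psi0 (1 - psi0))`, takes
#' `SE = SD(D_logOR) / sqrt(n)`, and exponentiates
#' `log OR +/- z_{alpha/2} SE`.
#'
#' @param tmle_out output of [tmle_update()].
#' @param level confidence level.
#' @return List `lower`, `upper`, `level`,
#'   `construction = "influence_curve"`, `se_log_or`.
#' @export
ci_influence_curve <- function(tmle_out, level = 0.95) {
  psi1 <- tmle_out$psi1; psi0 <- tmle_out$psi0
  if (psi1 <= PROB_CLIP || psi1 >= 1 - PROB_CLIP ||
      psi0 <= PROB_CLIP || psi0 >= 1 - PROB_CLIP) {
    stop("counterfactual mean at clipping boundary; influence-curve CI undefined",
         call. = FALSE)
  }
  d_log_or <- tmle_out$eic1 / (psi1 * (1 - psi1)) -
              tmle_out$eic0 / (psi0 * (1 - psi0))
  se <- sd(d_log_or) / sqrt(tmle_out$n)
  z <- qnorm(1 - (1 - level) / 2)
  log_or <- log(marginal_or(psi1, psi0))
  list(lower = exp(log_or - z * se), upper = exp(log_or + z * se),
       level = level, construction = "influence_curve", se_log_or = se)
}

# serialization ----------------------------------------------------------

#' Serialize estimate results
#'
#' @param results list of `estimate_result`s.
#' @param path output path; `.json` writes JSON, otherwise a
#'   forest-plot-ready TSV (method, OR, CI bounds).
#' @return `path`, invisibly.
#' @export
write_estimates <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, or = r$or,
               ci_lower = if (is.null(r$ci)) NA_real_ else r$ci$lower,
               ci_upper = if (is.null(r$ci)) NA_real_ else r$ci$upper,
               psi1 = r$psi1, psi0 = r$psi0, n = r$n,
               stringsAsFactors = FALSE)
  }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
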