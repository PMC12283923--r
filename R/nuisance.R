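# Nuisance estimation: outcome regression Q(A,W) = P(Y=1|A,W) and
# propensity g(W) = P(A=1|W), parametric or super-learner.

PROB_CLIP <- 1e-6

clip_prob <- function(p, eps = PROB_CLIP) pmin(pmax(p, eps), 1 - eps)

#' Truncate propensity scores
#'
#' Bounds estimated propensities to `[delta, 1 - delta]` as a positivity
#' guard; truncation events are counted in the `n_truncated` attribute.
#'
#' @param g estimated propensity scores.
#' @param delta truncation bound (default 0.025).
#' @return Truncated vector with attribute `n_truncated`.
#' @export
truncate_propensity <- function(g, delta = 0.025) {
  n_trunc <- sum(g < delta | g > 1 - delta)
  out <- pmin(pmax(g, delta), 1 - delta)
  attr(out, "n_truncated") <- n_trunc
  out
}

nuisance_response <- function(role, cohort) {
  if (role == "outcome") cohort$Y else cohort$A
}

nuisance_features <- function(role, cohort, design = NULL) {
  if (is.null(design)) design <- encode_design(cohort)
  if (role == "outcome") cbind(A = cohort$A, design) else design
}

# parametric fits --------------------------------------------------------

#' Fit a main-effects logistic nuisance model
#'
#' Outcome role: logistic regression of Y on exposure plus all encoded
#' covariates.  Propensity role: logistic regression of A on the covariates
#' only.  On (near-)separation the fit falls back to a ridge-stabilized
#' `glmnet` fit with a warning.
#'
#' @param role `"outcome"` or `"propensity"`.
#' @param cohort a `cohort_table`.
#' @param design optional pre-computed [encode_design()] matrix.
#' @param formula optional model formula over `.y` (the role's response),
#'   `A` and the design columns, overriding the main-effects default —
#'   e.g. `.y ~ A * Ki67` for a saturated fit on a discrete toy design.
#' @param start optional starting coefficients for the IRLS solver
#'   (intercept first); used to warm-start bootstrap refits.
#' @return A `nuisance_fit`.
#' @export
fit_parametric <- function(role = c("outcome", "propensity"), cohort,
                           design = NULL, formula = NULL, start = NULL) {
  role <- match.arg(role)
  check_both_arms(cohort)
  y <- nuisance_response(role, cohort)
  if (length(unique(y)) < 2L) {
    stop("both response classes must be present to fit the ", role, " model",
         call. = FALSE)
  }
  X <- nuisance_features(role, cohort, design)
  if (is.null(formula)) {
    # matrix-based IRLS (glm.fit): the default main-effects model skips
    # model.frame overhead, which matters inside the bootstrap
    X1 <- cbind("(Intercept)" = 1, X)
    fit <- suppressWarnings(
      glm.fit(X1, y, family = binomial(), start = start,
              control = glm.control(epsilon = 1e-10, maxit = 100)))
    beta <- fit$coefficients
    separated <- !fit$converged || any(abs(beta[-1L]) > 15, na.rm = TRUE)
    if (!separated) {
      beta[is.na(beta)] <- 0  # aliased (constant) columns drop out
      return(structure(list(role = role, kind = "parametric_matrix",
                            coefficients = beta, columns = colnames(X),
                            n = nrow(X), converged = fit$converged),
                       class = "nuisance_fit"))
    }
  } else {
    df <- data.frame(.y = y, X, check.names = FALSE)
    fit <- suppressWarnings(
      glm(formula, data = df, family = binomial(),
          control = glm.control(epsilon = 1e-10, maxit = 100))
    )
    separated <- !fit$converged ||
      any(abs(coef(fit)[-1L]) > 15, na.rm = TRUE)
    if (!separated) {
      return(structure(list(role = role, kind = "parametric", model = fit,
                            columns = colnames(X), n = nrow(X),
                            converged = fit$converged),
                       class = "nuisance_fit"))
    }
  }
  warning("apparent separation in ", role,
          " model; using ridge-stabilized fit", call. = FALSE)
  ridge <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 1e-3)
  structure(list(role = role, kind = "parametric_ridge",
                 model = ridge, columns = colnames(X),
                 n = nrow(X), converged = TRUE),
            class = "nuisance_fit")
}

#' @export
print.nuisance_fit <- function(x, ...) {
  cat(sprintf("<nuisance_fit> role = %s, learner = %s, n = %d\n",
              x$role, x$kind, x$n))
  invisible(x)
}

#' Predict conditional probabilities from a nuisance fit
#'
#' @param fit a `nuisance_fit` (parametric or super-learner).
#' @param cohort a `cohort_table` to predict on.
#' @param a for outcome fits: exposure level to predict under (`0`, `1`, or
#'   `NULL` for each patient's observed exposure).  Ignored for propensity
#'   fits.
#' @param design optional pre-computed design matrix.
#' @return Per-patient probabilities in `[0, 1]`.
#' @export
predict_nuisance <- function(fit, cohort, a = NULL, design = NULL) {
  if (is.null(design)) design <- encode_design(cohort, warn_constant = FALSE)
  if (fit$role == "outcome") {
    a_col <- if (is.null(a)) cohort$A else {
      if (!all(a %in% c(0, 1))) stop("exposure level must be 0 or 1",
                                     call. = FALSE)
      rep(a, length.out = nrow(design))
    }
    X <- cbind(A = a_col, design)
  } else {
    X <- design
  }
  X <- X[, fit$columns, drop = FALSE]
  p <- switch(fit$kind,
    parametric_matrix =
      plogis(drop(cbind(1, X) %*% fit$coefficients)),
    parametric = {
      df <- data.frame(X, check.names = FALSE)
      as.numeric(predict(fit$model, newdata = df, type = "response"))
    },
    parametric_ridge =
      as.numeric(predict(fit$model, newx = X, type = "response")),
    superlearner = predict_superlearner_matrix(fit, X)
  )
  pmin(pmax(p, 0), 1)
}

#' Counterfactual outcome predictions
#'
#' Returns `Q(a, W_i)` for every patient with exposure set to `a` —
#' the standardization step of G-computation.
#'
#' @param fit an outcome-role `nuisance_fit`.
#' @param cohort a `cohort_table`.
#' @param a exposure level, 0 or 1.
#' @return Per-patient probabilities.
#' @export
predict_counterfactual <- function(fit, cohort, a) {
  if (fit$role != "outcome") {
    stop("counterfactual prediction requires an outcome-role fit",
         call. = FALSE)
  }
  if (length(a) != 1L || !a %in% c(0, 1)) {
    stop("exposure level must be 0 or 1", call. = FALSE)
  }
  predict_nuisance(fit, cohort, a = a)
}

# learner registry -------------------------------------------------------

make_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "sl_learner")
}

#' Default super-learner registry
#'
#' Six base learners: random forest, k-nearest neighbours, RBF-kernel
#' support vector machine (with Platt-scaled probabilities fitted inside
#' the training fold via kernlab's internal 3-fold scheme), elastic-net
#' logistic regression, and two gradient-boosted-tree configurations
#' (shallow trees with moderate shrinkage; deeper trees with slower
#' shrinkage).  Hyperparameters are fixed documented defaults, overridable
#' via `hyper`.
#'
#' @param hyper optional named list overriding defaults: `rf_ntree`,
#'   `knn_k`, `svm_C`, `enet_alpha`, `xgb_shallow`, `xgb_deep` (each an
#'   xgboost parameter list plus `nrounds`).
#' @return Named list of learners.
#' @export
default_learner_registry <- function(hyper = list()) {
  h <- utils::modifyList(list(
    rf_ntree = 300L, knn_k = 25L, svm_C = 1,
    enet_alpha = 0.5, enet_nfolds = 5L,
    xgb_shallow = list(max_depth = 2, eta = 0.10, nrounds = 120,
                       subsample = 0.8),
    xgb_deep    = list(max_depth = 4, eta = 0.05, nrounds = 200,
                       subsample = 0.8)
  ), hyper)

  xgb_learner <- function(cfg) {
    make_learner("xgboost",
      fit = function(X, y, seed) {
        set.seed(seed)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = cfg$max_depth, eta = cfg$eta,
                        subsample = cfg$subsample, nthread = 1,
                        seed = seed),
          data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
          nrounds = cfg$nrounds, verbose = 0)
      },
      predict = function(m, X) {
        as.numeric(predict(m, xgboost::xgb.DMatrix(X, nthread = 1)))
      })
  }

  list(
    random_forest = make_learner("random_forest",
      fit = function(X, y, seed) {
        set.seed(seed)
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = h$rf_ntree)
      },
      predict = function(m, X) {
        clip_prob(as.numeric(predict(m, X, type = "prob")[, "1"]),
                  eps = 0.5 / h$rf_ntree)
      }),
    knn = make_learner("knn",
      fit = function(X, y, seed) {
        mu <- colMeans(X); sg <- apply(X, 2L, sd); sg[sg == 0] <- 1
        list(X = scale(X, mu, sg), y = y, mu = mu, sg = sg, k = h$knn_k)
      },
      predict = function(m, X) {
        Xs <- scale(X, m$mu, m$sg)
        pr <- class::knn(m$X, Xs, factor(m$y, levels = c(0, 1)),
                         k = m$k, prob = TRUE)
        win <- attr(pr, "prob")
        votes1 <- ifelse(pr == "1", win, 1 - win) * m$k
        (votes1 + 0.5) / (m$k + 1)   # Laplace-smoothed vote share
      }),
    ksvm = make_learner("ksvm",
      fit = function(X, y, seed) {
        set.seed(seed)
        kernlab::ksvm(X, factor(y, levels = c(0, 1)), kernel = "rbfdot",
                      C = h$svm_C, prob.model = TRUE)
      },
      predict = function(m, X) {
        as.numeric(kernlab::predict(m, X, type = "probabilities")[, "1"])
      }),
    elastic_net = make_learner("elastic_net",
      fit = function(X, y, seed) {
        set.seed(seed)
        glmnet::cv.glmnet(X, y, family = "binomial", alpha = h$enet_alpha,
                          nfolds = h$enet_nfolds)
      },
      predict = function(m, X) {
        as.numeric(predict(m, newx = X, s = "lambda.min",
                           type = "response"))
      }),
    xgb_shallow = xgb_learner(h$xgb_shallow),
    xgb_deep    = xgb_learner(h$xgb_deep)
  )
}

# cross-validation machinery ---------------------------------------------

# stratified fold assignment: random permutation within each stratum, then
# folds dealt round-robin, so every training fold keeps both classes
stratified_folds <- function(strata, folds, seed) {
  set.seed(seed)
  assignment <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

cv_risk <- function(p, y, loss = c("nll", "mse")) {
  loss <- match.arg(loss)
  p <- clip_prob(p)
  if (loss == "nll") -mean(y * log(p) + (1 - y) * log(1 - p))
  else mean((y - p)^2)
}

# convex weights minimizing the CV risk of the combination, via softmax
# reparameterization; started from uniform and from the best single
# learner, so the solution never does worse than the discrete argmin
solve_simplex_weights <- function(P, y, loss = "nll", tol = 1e-8) {
  L <- ncol(P)
  if (L == 1L) return(1)
  obj <- function(z) {
    w <- exp(z - max(z)); w <- w / sum(w)
    cv_risk(drop(P %*% w), y, loss)
  }
  best <- which.min(vapply(seq_len(L),
                           function(j) cv_risk(P[, j], y, loss), 0))
  starts <- list(rep(0, L), replace(rep(-8, L), best, 8))
  sols <- lapply(starts, function(z0) {
    optim(z0, obj, method = "BFGS",
          control = list(maxit = 500, reltol = tol))
  })
  z <- sols[[which.min(vapply(sols, `[[`, 0, "value"))]]$par
  w <- exp(z - max(z)); w <- w / sum(w)
  w[w < 1e-10] <- 0
  w / sum(w)
}

#' Fit a cross-validated super learner
#'
#' Stratified V-fold cross-validation (on the response, additionally on
#' exposure for the outcome role): each base learner is trained per fold
#' and its held-out probability predictions collected; the cross-validated
#' risk is the mean negative Bernoulli log-likelihood (predictions clipped
#' to `[1e-6, 1 - 1e-6]`); ensemble weights minimize the CV risk of the
#' convex combination over the simplex; base learners are then refit on
#' the full data.
#'
#' @param role `"outcome"` or `"propensity"`.
#' @param cohort a `cohort_table`.
#' @param design optional pre-computed design matrix.
#' @param folds number of CV folds (default 15).
#' @param seed integer seed controlling fold assignment and stochastic
#'   learners.
#' @param registry learner list, see [default_learner_registry()].
#' @param loss `"nll"` (default) or `"mse"`.
#' @return A `nuisance_fit` of kind `"superlearner"` with elements
#'   `weights`, `cv_risks`, `ensemble_cv_risk`, `fold_id`, `dropped`.
#' @export
fit_superlearner <- function(role = c("outcome", "propensity"), cohort,
                             design = NULL, folds = 15L, seed = 1L,
                             registry = default_learner_registry(),
                             loss = "nll") {
  role <- match.arg(role)
  check_both_arms(cohort)
  y <- nuisance_response(role, cohort)
  X <- nuisance_features(role, cohort, design)
  if (nrow(X) < folds * 4L) {
    stop("need at least 4 x folds observations for ", folds,
         "-fold cross-validation", call. = FALSE)
  }
  strata <- if (role == "outcome") interaction(y, cohort$A) else y
  fold_id <- stratified_folds(strata, folds, seed)

  L <- length(registry)
  P <- matrix(NA_real_, nrow(X), L,
              dimnames = list(NULL, names(registry)))
  failed <- setNames(logical(L), names(registry))
  for (v in seq_len(folds)) {
    tr <- fold_id != v; te <- !tr
    if (length(unique(y[tr])) < 2L) {
      stop("training fold ", v, " lost a response class; reduce folds",
           call. = FALSE)
    }
    for (j in seq_len(L)) {
      if (failed[j]) next
      lr <- registry[[j]]
      p <- tryCatch({
        m <- lr$fit(X[tr, , drop = FALSE], y[tr],
                    seed = seed_offset(seed, 1000L * v + j))
        lr$predict(m, X[te, , drop = FALSE])
      }, error = function(e) e)
      if (inherits(p, "error")) {
        failed[j] <- TRUE
        warning(sprintf("learner '%s' failed on fold %d (%s); dropped",
                        names(registry)[j], v, conditionMessage(p)),
                call. = FALSE)
      } else {
        P[te, j] <- p
      }
    }
  }
  keep <- !failed
  if (!any(keep)) stop("all super-learner base learners failed",
                       call. = FALSE)
  P <- P[, keep, drop = FALSE]
  cv_risks <- apply(P, 2L, cv_risk, y = y, loss = loss)
  w <- solve_simplex_weights(P, y, loss)
  ens_risk <- cv_risk(drop(P %*% w), y, loss)

  full_fits <- lapply(which(keep), function(j) {
    registry[[j]]$fit(X, y, seed = seed_offset(seed, 9000L + j))
  })
  names(full_fits) <- names(registry)[keep]

  structure(list(role = role, kind = "superlearner",
                 columns = colnames(X), n = nrow(X),
                 registry = registry[keep], full_fits = full_fits,
                 weights = setNames(w, names(registry)[keep]),
                 cv_risks = cv_risks, ensemble_cv_risk = ens_risk,
                 fold_id = fold_id, folds = folds, loss = loss,
                 seed = seed, dropped = names(registry)[!keep],
                 cv_predictions = P, response = y),
            class = "nuisance_fit")
}

predict_superlearner_matrix <- function(fit, X) {
  preds <- vapply(names(fit$full_fits), function(nm) {
    fit$registry[[nm]]$predict(fit$full_fits[[nm]], X)
  }, numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  clip_prob(drop(preds %*% fit$weights))
}

#' Serialize a super-learner audit record
#'
#' Writes the learner roster, per-learner cross-validated risks, ensemble
#' weights, fold count and any dropped learners to JSON.
#'
#' @param fit a super-learner `nuisance_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_superlearner_audit <- function(fit, path) {
  if (fit$kind != "superlearner") {
    stop("audit record is defined for super-learner fits", call. = FALSE)
  }
  payload <- list(role = fit$role, n = fit$n, folds = fit$folds,
                  loss = fit$loss, seed = fit$seed,
                  cv_risks = as.list(fit$cv_risks),
                  weights = as.list(fit$weights),
                  ensemble_cv_risk = fit$ensemble_cv_risk,
                  dropped = fit$dropped)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
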