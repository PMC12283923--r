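# Assumption diagnostics: positivity via effective sample size, covariate
# balance via standardized mean differences, and a confounding-function
# sensitivity analysis for unmeasured confounding.

#' Effective sample size of a weighted sample
#'
#' `ESS = (sum w)^2 / sum w^2` — the number of equally weighted
#' observations carrying the same information.  A ratio `ESS / n` near 1
#' within each exposure arm indicates similar weights and adequate overlap.
#'
#' @param weights positive per-patient weights.
#' @param arm optional logical/0-1 mask restricting to one exposure arm.
#' @return List `ess`, `n`, `ratio`.
#' @export
effective_sample_size <- function(weights, arm = NULL) {
  if (!is.null(arm)) weights <- weights[as.logical(arm)]
  if (length(weights) == 0L) stop("empty exposure arm", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  ess <- sum(weights)^2 / sum(weights^2)
  list(ess = ess, n = length(weights), ratio = ess / length(weights))
}

#' Standardized mean difference of a covariate between exposure arms
#'
#' `SMD = (weighted mean exposed - weighted mean unexposed) / pooled SD`,
#' with the pooled denominator `sqrt((s1^2 + s0^2) / 2)` computed from the
#' *unweighted* arm SDs in both the unweighted and weighted case, so
#' before/after values are comparable.
#'
#' @param cohort a `cohort_table`.
#' @param covariate a design-matrix column name (see [encode_design()]).
#' @param weights optional per-patient weights; `NULL` means unweighted.
#' @return The SMD (0, with a `"note"` attribute, when the pooled SD is 0).
#' @export
standardized_mean_difference <- function(cohort, covariate,
                                         weights = NULL) {
  X <- encode_design(cohort)
  if (!covariate %in% colnames(X)) {
    stop("unknown covariate '", covariate, "'", call. = FALSE)
  }
  x <- X[, covariate]
  a <- cohort$A
  if (is.null(weights)) weights <- rep(1, length(x))
  m1 <- sum(weights[a == 1] * x[a == 1]) / sum(weights[a == 1])
  m0 <- sum(weights[a == 0] * x[a == 0]) / sum(weights[a == 0])
  pooled_sd <- sqrt((var(x[a == 1]) + var(x[a == 0])) / 2)
  if (!is.finite(pooled_sd) || pooled_sd == 0) {
    return(structure(0, note = "zero pooled SD"))
  }
  (m1 - m0) / pooled_sd
}

#' Covariate balance and weight diagnostics
#'
#' Standardized mean differences for every design column before and after
#' weighting, plus a weight summary: range, per-arm effective sample size
#' and ESS/n ratio.
#'
#' @param cohort a `cohort_table`.
#' @param weights per-patient weights (e.g. the IPTW weights from
#'   [estimate_iptw()]'s diagnostics).
#' @return A `balance_table`: data.frame of SMDs with the weight summary
#'   in attribute `weight_summary`.
#' @export
balance_table <- function(cohort, weights) {
  cols <- colnames(encode_design(cohort))
  smd_before <- vapply(cols, function(v)
    as.numeric(standardized_mean_difference(cohort, v)), 0)
  smd_after <- vapply(cols, function(v)
    as.numeric(standardized_mean_difference(cohort, v, weights)), 0)
  a <- cohort$A
  ws <- list(min = min(weights), max = max(weights),
             ess_exposed = effective_sample_size(weights, a == 1),
             ess_unexposed = effective_sample_size(weights, a == 0))
  structure(data.frame(covariate = cols, smd_unweighted = smd_before,
                       smd_weighted = smd_after, row.names = NULL,
                       stringsAsFactors = FALSE),
            weight_summary = ws,
            class = c("balance_table", "data.frame"))
}

#' @export
print.balance_table <- function(x, ...) {
  ws <- attr(x, "weight_summary")
  cat("<balance_table>\n")
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("weights in [%.3f, %.3f]; ESS/n exposed %.3f, unexposed %.3f\n",
              ws$min, ws$max, ws$ess_exposed$ratio,
              ws$ess_unexposed$ratio))
  invisible(x)
}

#' Confounding-function sensitivity analysis
#'
#' Quantifies how strong unmeasured confounding would have to be to
#' change the conclusion.  The confounding functions are taken constant in
#' W: `c1` is the assumed difference in mean potential outcome Y(1)
#' between exposed and unexposed patients, `c0` the analogue for Y(0),
#' both on the risk scale.  The bias-corrected means are
#' `psi1_c = psi1 - c1 P(A=0)` and `psi0_c = psi0 + c0 P(A=1)`, and the
#' odds ratio is recomputed on a grid of `(c1, c0)`; `(0, 0)` reproduces
#' the baseline estimate exactly.
#'
#' @param cohort a `cohort_table`.
#' @param estimator function `cohort -> estimate_result` giving the
#'   baseline (e.g. `estimate_gc`).
#' @param c1_range,c0_range symmetric ranges for the two confounding
#'   functions.
#' @param grid_size points per axis.
#' @return A `sensitivity_grid`: long data.frame `c1`, `c0`, `or`,
#'   `clamped`, `crosses_null`; baseline estimate in attribute
#'   `baseline`.
#' @export
sensitivity_contour <- function(cohort, estimator,
                                c1_range = c(-0.05, 0.05),
                                c0_range = c(-0.05, 0.05),
                                grid_size = 21L) {
  base <- estimator(cohort)
  p_exposed <- mean(cohort$A)
  c1s <- seq(c1_range[1L], c1_range[2L], length.out = grid_size)
  c0s <- seq(c0_range[1L], c0_range[2L], length.out = grid_size)
  grid <- expand.grid(c1 = c1s, c0 = c0s)
  psi1c <- base$psi1 - grid$c1 * (1 - p_exposed)
  psi0c <- base$psi0 + grid$c0 * p_exposed
  clamped <- psi1c <= PROB_CLIP | psi1c >= 1 - PROB_CLIP |
             psi0c <= PROB_CLIP | psi0c >= 1 - PROB_CLIP
  if (all(clamped)) {
    stop("corrected means fall outside (0, 1) everywhere; narrow the ranges",
         call. = FALSE)
  }
  psi1c <- clip_prob(psi1c)
  psi0c <- clip_prob(psi0c)
  or <- (psi1c * (1 - psi0c)) / ((1 - psi1c) * psi0c)
  grid$or <- or
  grid$clamped <- clamped
  grid$crosses_null <- sign(or - 1) != sign(base$or - 1)
  structure(grid, baseline = base, p_exposed = p_exposed,
            class = c("sensitivity_grid", "data.frame"))
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  base <- attr(x, "baseline")
  cat(sprintf("<sensitivity_grid> %d points; baseline %s OR = %.4f; OR range [%.4f, %.4f]; null crossed at %d point(s)\n",
              nrow(x), base$method, base$or, min(x$or), max(x$or),
              sum(x$crosses_null)))
  invisible(x)
}

#' Serialize diagnostics tables
#'
#' @param x a `balance_table` or `sensitivity_grid`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
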