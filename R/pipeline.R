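# Orchestration: one config drives descriptives, the four estimators on
# each sensitivity subset, balance diagnostics and the confounding-function
# contour, emitting a machine-readable report.

#' Build and validate an analysis configuration
#'
#' @param input either a cohort CSV path (`list(csv = path)` or a character
#'   path) or a [generator_spec()] for synthetic runs.
#' @param estimators subset of `c("GC", "IPTW", "TMLE", "TMLE_SL")`.
#' @param subsets subset rules, see [filter_subset()].
#' @param B bootstrap replicates (>= 200 whenever a bootstrap CI is
#'   requested).
#' @param folds super-learner folds.
#' @param sl_learners names from [default_learner_registry()] to use for
#'   TMLE_SL.
#' @param delta propensity truncation bound.
#' @param sensitivity run the confounding-function contour
#'   ([sensitivity_contour()] on the GC estimator).
#' @param seed mandatory integer seed.
#' @param output_dir optional directory for serialized outputs.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input,
                            estimators = c("GC", "IPTW", "TMLE", "TMLE_SL"),
                            subsets = c("all", "exclude_stage_III",
                                        "exclude_age_ge_70"),
                            B = 1000L, folds = 15L,
                            sl_learners = names(default_learner_registry()),
                            delta = 0.025, sensitivity = TRUE,
                            seed = NULL, output_dir = NULL) {
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  estimators <- match.arg(estimators, several.ok = TRUE)
  subsets <- match.arg(subsets, several.ok = TRUE)
  if (any(estimators %in% c("GC", "IPTW", "TMLE")) && B < 200L) {
    stop("B >= 200 required for bootstrap confidence intervals",
         call. = FALSE)
  }
  if (is.character(input)) input <- list(csv = input)
  if (!inherits(input, "generator_spec") && is.null(input$csv)) {
    stop("input must be a CSV path or a generator_spec", call. = FALSE)
  }
  bad <- setdiff(sl_learners, names(default_learner_registry()))
  if (length(bad) > 0L) {
    stop("unknown learner(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(input = input, estimators = estimators, subsets = subsets,
                 B = as.integer(B), folds = as.integer(folds),
                 sl_learners = sl_learners, delta = delta,
                 sensitivity = sensitivity, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "analysis_config")
}

run_one_estimator <- function(method, cohort, config, seed) {
  switch(method,
    GC = {
      res <- estimate_gc(cohort)
      res$ci <- ci_bootstrap(cohort, estimate_gc, B = config$B,
                             seed = seed)
      res
    },
    IPTW = {
      res <- estimate_iptw(cohort, delta = config$delta)
      res$ci <- ci_bootstrap(
        cohort, function(c) estimate_iptw(c, delta = config$delta),
        B = config$B, seed = seed)
      res
    },
    TMLE = estimate_tmle(cohort, "parametric", seed = seed,
                         delta = config$delta, ci = "bootstrap",
                         B = config$B),
    TMLE_SL = estimate_tmle(
      cohort, "superlearner", seed = seed, folds = config$folds,
      registry = default_learner_registry()[config$sl_learners],
      delta = config$delta, ci = "influence_curve")
  )
}

#' Run the full analysis pipeline
#'
#' Ingests (or synthesizes) the cohort, computes the descriptive battery,
#' runs every requested estimator on every requested subset (nuisance
#' models refit from scratch per subset), IPTW balance diagnostics, and
#' the confounding-function sensitivity contour.  Deterministic given the
#' config seed; per-cell failures are recorded in the report and the run
#' continues.
#'
#' @param config an [analysis_config()].
#' @return An `analysis_report` list: `descriptives`, `estimates`
#'   (per subset x method), `balance`, `sensitivity`, `provenance`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- if (inherits(config$input, "generator_spec")) {
    generate_cohort(config$input)
  } else {
    read_cohort(config$input$csv)
  }

  report <- list(
    descriptives = describe(cohort),
    estimates = list(), balance = NULL, sensitivity = NULL,
    guards = list(),
    provenance = list(
      package_version = as.character(utils::packageVersion("causalor")),
      seed = config$seed, n = nrow(cohort),
      config_hash = config_hash(config),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )

  for (rule in config$subsets) {
    sub <- filter_subset(cohort, rule)
    cell <- list()
    for (method in config$estimators) {
      seed_cell <- seed_offset(config$seed,
                               match(rule, config$subsets) * 100L +
                                 match(method, config$estimators))
      cell[[method]] <- tryCatch(
        run_one_estimator(method, sub, config, seed_cell),
        error = function(e) list(method = method, failed = TRUE,
                                 message = conditionMessage(e)))
    }
    report$estimates[[rule]] <- cell
  }

  iptw <- report$estimates[["all"]][["IPTW"]]
  if (!is.null(iptw) && is.null(iptw$failed)) {
    report$balance <- balance_table(cohort, iptw$diagnostics$weights)
    report$guards$iptw_truncated <- iptw$diagnostics$n_truncated
  }
  if (isTRUE(config$sensitivity)) {
    report$sensitivity <- tryCatch(
      sensitivity_contour(cohort, estimate_gc),
      error = function(e) list(failed = TRUE,
                               message = conditionMessage(e)))
  }
  class(report) <- "analysis_report"

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

config_hash <- function(config) {
  x <- config
  x$output_dir <- NULL
  paste0("cfg-", sum(utf8ToInt(paste(deparse(x), collapse = ""))))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> n = %d, seed = %d\n",
              x$provenance$n, x$provenance$seed))
  for (rule in names(x$estimates)) {
    cat("subset:", rule, "\n")
    for (m in names(x$estimates[[rule]])) {
      r <- x$estimates[[rule]][[m]]
      if (isTRUE(r$failed)) {
        cat(sprintf("  %-8s FAILED: %s\n", m, r$message))
      } else if (!is.null(r$ci)) {
        cat(sprintf("  %-8s OR = %.3f  95%% CI [%.3f, %.3f]\n",
                    m, r$or, r$ci$lower, r$ci$upper))
      } else {
        cat(sprintf("  %-8s OR = %.3f\n", m, r$or))
      }
    }
  }
  invisible(x)
}

report_to_list <- function(report) {
  est <- lapply(report$estimates, function(cell) {
    lapply(cell, function(r) {
      if (isTRUE(r$failed)) {
        list(method = r$method, failed = TRUE, message = r$message)
      } else {
        list(method = r$method, psi1 = r$psi1, psi0 = r$psi0, or = r$or,
             ci = if (is.null(r$ci)) NULL else
               r$ci[c("lower", "upper", "level", "construction")],
             n = r$n, epsilon = as.list(r$epsilon))
      }
    })
  })
  list(
    descriptives = as.data.frame(report$descriptives),
    estimates = est,
    balance = if (is.null(report$balance)) NULL else
      as.data.frame(report$balance),
    sensitivity = if (is.null(report$sensitivity) ||
                      isTRUE(report$sensitivity$failed)) NULL else
      as.data.frame(report$sensitivity),
    guards = report$guards,
    provenance = report$provenance
  )
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full report), `descriptives.tsv`, one
#' forest-plot TSV per subset, `balance.tsv` and `sensitivity.tsv`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_descriptive_report(report$descriptives,
                           file.path(dir, "descriptives.tsv"))
  for (rule in names(report$estimates)) {
    ok <- Filter(function(r) !isTRUE(r$failed), report$estimates[[rule]])
    if (length(ok) > 0L) {
      write_estimates(ok, file.path(dir, paste0("forest_", rule, ".tsv")))
    }
  }
  if (!is.null(report$balance)) {
    write_diagnostics(report$balance, file.path(dir, "balance.tsv"))
  }
  if (!is.null(report$sensitivity) &&
      !isTRUE(report$sensitivity$failed)) {
    write_diagnostics(report$sensitivity,
                      file.path(dir, "sensitivity.tsv"))
  }
  invisible(dir)
}

#' Structural validation of a serialized report
#'
#' Checks a report list (e.g. re-read from `report.json`) against the
#' schema shipped at `inst/schema/analysis_report_schema.json`: required
#' top-level blocks, required estimate fields, numeric OR and CI ordering.
#'
#' @param x report list (from [jsonlite::read_json()] with
#'   `simplifyVector = TRUE`).
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_report <- function(x) {
  need <- c("descriptives", "estimates", "provenance")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("report missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (rule in names(x$estimates)) {
    for (m in names(x$estimates[[rule]])) {
      r <- x$estimates[[rule]][[m]]
      if (isTRUE(r$failed)) {
        if (is.null(r$message)) stop("failure record without message",
                                     call. = FALSE)
        next
      }
      if (!is.numeric(r$or) || r$or <= 0) {
        stop(sprintf("estimate %s/%s: invalid OR", rule, m),
             call. = FALSE)
      }
      if (!is.null(r$ci) && r$ci$lower > r$ci$upper) {
        stop(sprintf("estimate %s/%s: CI bounds out of order", rule, m),
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
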