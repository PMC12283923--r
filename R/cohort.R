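#' @importFrom stats aov ave chisq.test fisher.test glm glm.control p.adjust
#'   plogis pnorm predict qlogis qnorm quantile rbinom rnorm sd shapiro.test
#'   t.test var wilcox.test binomial coef optim setNames complete.cases
#' @importFrom utils read.csv write.csv
NULL

# canonical analysis variables -------------------------------------------

#' Canonical cohort column names
#'
#' The eleven adjustment covariates plus outcome and exposure used throughout
#' the package.  `Y` is the 5-year all-cause mortality indicator, `A` the
#' diabetes indicator, and `stage` the AJCC stage recorded as `"I"`, `"II"`
#' or `"III"`.
#'
#' @return Named list with components `outcome`, `exposure`, `continuous`,
#'   `binary`, `ordinal` and `all`.
#' @export
cohort_fields <- function() {
  list(
    outcome    = "Y",
    exposure   = "A",
    continuous = c("age", "BMI"),
    binary     = c("Ki67", "P53", "HER2", "ER", "PR",
                   "lymphatic_metastasis", "hypertension", "menopause"),
    ordinal    = "stage",
    all        = c("Y", "A", "age", "BMI", "Ki67", "P53", "HER2", "ER", "PR",
                   "lymphatic_metastasis", "hypertension", "menopause",
                   "stage")
  )
}

stage_levels <- function() c("I", "II", "III")

# constructor / validator ------------------------------------------------

#' Construct and validate a cohort table
#'
#' Validates a data frame of patient records against the analysis schema:
#' complete cases only, `{0,1}` coding for the outcome, exposure and the
#' eight binary covariates, and stage in `{I, II, III}`.
#'
#' @param data data.frame holding at least the canonical columns
#'   (see [cohort_fields()]).
#' @param drop_incomplete drop rows with missing analysis variables
#'   (complete-case rule) with a warning, rather than erroring.
#' @return A `cohort_table`: a data.frame restricted to the canonical
#'   columns, with attribute `n_dropped` recording complete-case removals.
#' @export
cohort_table <- function(data, drop_incomplete = TRUE) {
  fl <- cohort_fields()
  missing_cols <- setdiff(fl$all, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[, fl$all]
  data$stage <- as.character(data$stage)

  cc <- complete.cases(data)
  n_dropped <- sum(!cc)
  if (n_dropped > 0L) {
    if (!drop_incomplete) stop("cohort contains missing values", call. = FALSE)
    warning(sprintf("dropped %d row(s) with missing analysis variables",
                    n_dropped), call. = FALSE)
    data <- data[cc, , drop = FALSE]
  }

  for (v in c(fl$outcome, fl$exposure, fl$binary)) {
    bad <- which(!(data[[v]] %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop(sprintf("validation error: non-binary value in '%s' at row %d",
                   v, bad[1L]), call. = FALSE)
    }
  }
  bad_stage <- which(!(data$stage %in% stage_levels()))
  if (length(bad_stage) > 0L) {
    stop(sprintf("validation error: stage '%s' at row %d not in {I, II, III}",
                 data$stage[bad_stage[1L]], bad_stage[1L]), call. = FALSE)
  }
  for (v in fl$continuous) {
    if (!is.numeric(data[[v]])) {
      stop(sprintf("validation error: '%s' must be numeric", v),
           call. = FALSE)
    }
  }

  rownames(data) <- NULL
  structure(data, n_dropped = n_dropped,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients (%d exposed, %d deaths)\n",
              nrow(x), sum(x$A), sum(x$Y)))
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0L) {
    cat(sprintf("  %d row(s) dropped as incomplete at ingestion\n", nd))
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

check_both_arms <- function(cohort) {
  if (nrow(cohort) < 2L || length(unique(cohort$A)) < 2L) {
    stop("positivity error: cohort must contain both exposure levels",
         call. = FALSE)
  }
  invisible(TRUE)
}

# I/O --------------------------------------------------------------------

#' Read a cohort from CSV
#'
#' Reads an RFC-4180 CSV with a header row, renames columns via `schema`,
#' and validates the result (complete-case; see [cohort_table()]).
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical field names to
#'   file column names, e.g. `c(Y = "death5y")`.  Unmapped canonical names
#'   are looked up verbatim.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        stop(sprintf("cohort schema error: column '%s' (for '%s') not in %s",
                     src, canon, path), call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  cohort_table(raw)
}

#' Write a cohort to CSV
#'
#' @param cohort a `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# design encoding --------------------------------------------------------

#' Encode the covariate design matrix
#'
#' Fixed column order: `age`, `BMI`, the eight binary indicators
#' (`Ki67`, `P53`, `HER2`, `ER`, `PR`, `lymphatic_metastasis`,
#' `hypertension`, `menopause`), then treatment-coded stage dummies
#' `stage_II` and `stage_III` (stage I is the reference level).
#'
#' @param cohort a `cohort_table`.
#' @param warn_constant warn on constant columns (internal callers skip
#'   the check; learners must tolerate constants either way).
#' @return Numeric matrix, one row per patient, 12 columns.
#' @export
encode_design <- function(cohort, warn_constant = TRUE) {
  fl <- cohort_fields()
  X <- cbind(
    as.matrix(as.data.frame(cohort)[, c(fl$continuous, fl$binary)]),
    stage_II  = as.numeric(cohort$stage == "II"),
    stage_III = as.numeric(cohort$stage == "III")
  )
  storage.mode(X) <- "double"
  if (warn_constant) {
    const <- colnames(X)[vapply(seq_len(ncol(X)),
                                function(j) all(X[, j] == X[1L, j]), TRUE)]
    if (length(const) > 0L) {
      warning("constant design column(s): ", paste(const, collapse = ", "),
              call. = FALSE)
    }
  }
  X
}

# subsets ----------------------------------------------------------------

#' Filter a cohort by a named subset rule
#'
#' The two sensitivity subsets drop stage-III disease or patients aged 70
#' and over; `"all"` is the identity.
#'
#' @param cohort a `cohort_table`.
#' @param rule one of `"all"`, `"exclude_stage_III"`, `"exclude_age_ge_70"`.
#' @return A `cohort_table` containing the retained rows.
#' @export
filter_subset <- function(cohort,
                          rule = c("all", "exclude_stage_III",
                                   "exclude_age_ge_70")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
    all               = rep(TRUE, nrow(cohort)),
    exclude_stage_III = cohort$stage != "III",
    exclude_age_ge_70 = cohort$age < 70
  )
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped = 0L, class = c("cohort_table", "data.frame"))
}

# descriptive battery ----------------------------------------------------

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Levene's test: one-way ANOVA on absolute deviations from the group mean.
levene_test <- function(x, g) {
  g <- factor(g)
  dev <- abs(x - ave(x, g))
  fit <- aov(dev ~ g)
  summary(fit)[[1L]][["Pr(>F)"]][1L]
}

# Shapiro-Wilk is defined for 3..5000 observations; larger groups are
# thinned evenly over the sorted values so the gate stays
# permutation-invariant and deterministic.
shapiro_p <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 3L) return(NA_real_)
  if (n > 5000L) x <- x[unique(round(seq(1L, n, length.out = 5000L)))]
  if (length(unique(x)) < 3L) return(0)
  shapiro.test(x)$p.value
}

fmt_mean_sd <- function(x) {
  sprintf("%.2f (%.2f)", mean(x), sd(x))
}
fmt_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
  sprintf("%.2f (%.2f, %.2f)", q[2L], q[1L], q[3L])
}
fmt_count_pct <- function(k, n) {
  sprintf("%d (%.2f%%)", k, round_half_up(100 * k / n, 2L))
}

describe_continuous <- function(x, a) {
  x1 <- x[a == 1]; x0 <- x[a == 0]
  if (sd(x) == 0) {
    return(list(test = "skipped (zero variance)", p = NA_real_,
                normal = NA, overall = fmt_mean_sd(x),
                unexposed = fmt_mean_sd(x0), exposed = fmt_mean_sd(x1)))
  }
  normal <- isTRUE(shapiro_p(x1) >= 0.05) && isTRUE(shapiro_p(x0) >= 0.05)
  if (normal) {
    lev_p <- levene_test(x, a)
    pooled <- isTRUE(lev_p >= 0.05)
    p <- t.test(x1, x0, var.equal = pooled)$p.value
    test <- if (pooled) "t-test (pooled)" else "t-test (Welch)"
    fmt <- fmt_mean_sd
  } else {
    p <- wilcox.test(x1, x0, exact = FALSE, correct = TRUE)$p.value
    test <- "Mann-Whitney U"
    fmt <- fmt_median_iqr
  }
  list(test = test, p = p, normal = normal, overall = fmt(x),
       unexposed = fmt(x0), exposed = fmt(x1))
}

describe_categorical <- function(x, a, level) {
  k  <- as.numeric(x == level)
  tab <- table(factor(k, levels = c(0, 1)), factor(a, levels = c(0, 1)))
  expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
  if (any(expected < 5)) {
    p <- fisher.test(tab)$p.value
    test <- "Fisher exact"
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
    test <- "chi-square"
  }
  list(test = test, p = p,
       overall   = fmt_count_pct(sum(k), length(k)),
       unexposed = fmt_count_pct(sum(k[a == 0]), sum(a == 0)),
       exposed   = fmt_count_pct(sum(k[a == 1]), sum(a == 1)),
       pct_overall   = round_half_up(100 * mean(k), 2L),
       pct_unexposed = round_half_up(100 * mean(k[a == 0]), 2L),
       pct_exposed   = round_half_up(100 * mean(k[a == 1]), 2L))
}

#' Descriptive statistics battery by exposure group
#'
#' Summarises each analysis variable overall and by exposure arm.
#' Continuous variables are gated per arm by the Shapiro-Wilk test at
#' alpha = 0.05: both arms normal gives a t-test (pooled or Welch chosen by
#' Levene's homogeneity test at 0.05) and mean (SD) display; otherwise a
#' Mann-Whitney U test and median (IQR) display.  Categorical variables get
#' a continuity-corrected chi-square test, replaced by Fisher's exact test
#' whenever any expected cell count is below 5.  Raw p-values are
#' Benjamini-Hochberg adjusted across the battery.  Percentages are
#' count/group-n x 100, rounded half-up to two decimals.
#'
#' @param cohort a `cohort_table` with both exposure arms non-empty.
#' @return A `descriptive_report`: data.frame with one row per variable
#'   (stage contributes one row per level) holding the formatted summaries,
#'   percentage columns for categorical rows, test name, raw and
#'   BH-adjusted p-values.  Group sizes are kept in attributes
#'   `n_overall`, `n_unexposed`, `n_exposed`.
#' @export
describe <- function(cohort) {
  check_both_arms(cohort)
  fl <- cohort_fields()
  a <- cohort$A
  rows <- list()

  add_row <- function(variable, d) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = d$test, p_raw = d$p,
      overall = d$overall, unexposed = d$unexposed, exposed = d$exposed,
      pct_overall   = if (is.null(d$pct_overall)) NA_real_ else d$pct_overall,
      pct_unexposed = if (is.null(d$pct_unexposed)) NA_real_ else d$pct_unexposed,
      pct_exposed   = if (is.null(d$pct_exposed)) NA_real_ else d$pct_exposed,
      stringsAsFactors = FALSE
    )
  }

  add_row("5-year mortality", describe_categorical(cohort$Y, a, 1))
  for (v in fl$continuous)  add_row(v, describe_continuous(cohort[[v]], a))
  for (v in fl$binary)      add_row(v, describe_categorical(cohort[[v]], a, 1))
  for (s in stage_levels()) {
    add_row(paste0("stage ", s), describe_categorical(cohort$stage, a, s))
  }

  out <- do.call(rbind, rows)
  # BH across the battery; stage enters the adjustment once per level as
  # displayed, matching a per-row test battery
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  structure(out,
            n_overall = nrow(cohort), n_unexposed = sum(a == 0),
            n_exposed = sum(a == 1),
            class = c("descriptive_report", "data.frame"))
}

#' @export
print.descriptive_report <- function(x, ...) {
  cat(sprintf("<descriptive_report> N = %d (unexposed %d, exposed %d)\n",
              attr(x, "n_overall"), attr(x, "n_unexposed"),
              attr(x, "n_exposed")))
  df <- as.data.frame(x)[, c("variable", "overall", "unexposed", "exposed",
                             "test", "p_raw", "p_adjusted")]
  df$p_raw <- signif(df$p_raw, 3L)
  df$p_adjusted <- signif(df$p_adjusted, 3L)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a descriptive report
#'
#' @param report a `descriptive_report`.
#' @param path output path; `.json` writes JSON, anything else
#'   tab-separated text.
#' @return `path`, invisibly.
#' @export
write_descriptive_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    payload <- list(
      n = list(overall = attr(report, "n_overall"),
               unexposed = attr(report, "n_unexposed"),
               exposed = attr(report, "n_exposed")),
      rows = as.data.frame(report)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
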