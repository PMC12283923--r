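# Cohort fixtures built in code.

# fully specified cohort from vectors; unspecified covariates held constant
make_cohort <- function(Y, A, Ki67 = 0, age = 50, BMI = 24, stage = "I",
                        P53 = 0, HER2 = 1, ER = 1, PR = 1,
                        lymphatic_metastasis = 0, hypertension = 0,
                        menopause = 0) {
  n <- length(Y)
  df <- data.frame(Y = Y, A = A,
                   age = rep_len(age, n), BMI = rep_len(BMI, n),
                   Ki67 = rep_len(Ki67, n), P53 = rep_len(P53, n),
                   HER2 = rep_len(HER2, n), ER = rep_len(ER, n),
                   PR = rep_len(PR, n),
                   lymphatic_metastasis = rep_len(lymphatic_metastasis, n),
                   hypertension = rep_len(hypertension, n),
                   menopause = rep_len(menopause, n),
                   stage = rep_len(stage, n))
  suppressWarnings(cohort_table(df))
}

# small random cohort with signal in every field
toy_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  make_cohort(Y = rbinom(n, 1, 0.3), A = rbinom(n, 1, 0.4),
              Ki67 = rbinom(n, 1, 0.5), age = round(rnorm(n, 50, 8), 1),
              BMI = round(rnorm(n, 24, 3), 1),
              stage = sample(c("I", "II", "III"), n, replace = TRUE),
              P53 = rbinom(n, 1, 0.4), HER2 = rbinom(n, 1, 0.7),
              ER = rbinom(n, 1, 0.7), PR = rbinom(n, 1, 0.6),
              lymphatic_metastasis = rbinom(n, 1, 0.6),
              hypertension = rbinom(n, 1, 0.3),
              menopause = rbinom(n, 1, 0.5))
}

# cohort reproducing the printed 2x2 counts: 3386 patients, 300 exposed,
# deaths 34/300 and 181/3086, stage III 58/300 and 417/3086
reference_counts_cohort <- function() {
  a <- rep(c(1, 0), c(300, 3086))
  y <- c(rep(c(1, 0), c(34, 266)), rep(c(1, 0), c(181, 2905)))
  stage <- c(rep(c("III", "I"), c(58, 242)), rep(c("III", "I"), c(417, 2669)))
  make_cohort(Y = y, A = a, stage = stage,
              Ki67 = rep(c(1, 0), length.out = 3386),
              age = rep(c(48, 52, 55), length.out = 3386))
}

write_cohort_csv <- function(cohort, path = tempfile(fileext = ".csv")) {
  write_cohort(cohort, path)
  path
}

# 20-row discrete toy with one varying binary covariate and all four
# (A, W) cells populated, for saturated-model oracle checks
discrete_toy <- function() {
  make_cohort(
    Y    = c(1, 0, 0, 1, 0, 0, 0, 1, 1, 0, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0),
    A    = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    Ki67 = c(1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 0, 0, 1)
  )
}
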