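# Independent oracles, kept free of the package's estimation code paths.

# brute-force nonparametric standardization over the empirical covariate
# distribution: psi_a = sum_w Phat(W = w) * mean(Y | A = a, W = w)
oracle_standardize <- function(Y, A, W, a) {
  W <- as.data.frame(W)
  key <- do.call(paste, c(W, sep = "\r"))
  psi <- 0
  for (w in unique(key)) {
    in_cell <- key == w
    cell_mean <- mean(Y[in_cell & A == a])
    psi <- psi + mean(in_cell) * cell_mean
  }
  psi
}

# Hajek weighted-mean closed form from explicit propensities
oracle_hajek <- function(Y, A, g) {
  w1 <- (A / g)[A == 1]
  w0 <- ((1 - A) / (1 - g))[A == 0]
  list(psi1 = sum(w1 * Y[A == 1]) / sum(w1),
       psi0 = sum(w0 * Y[A == 0]) / sum(w0))
}

oracle_or <- function(psi1, psi0) (psi1 * (1 - psi0)) / ((1 - psi1) * psi0)

# direct-integration truth oracle: exact enumeration of the discrete
# covariate cells crossed with Gauss-Hermite quadrature for age and BMI
# (clamped normals: node values clamped like the generator's draws)
oracle_truth_integration <- function(spec, nodes = 60) {
  gh <- pracma::gaussHermite(nodes)
  age <- pmin(pmax(sqrt(2) * spec$age_sd * gh$x + spec$age_mean, 25), 85)
  bmi <- pmin(pmax(sqrt(2) * spec$bmi_sd * gh$x + spec$bmi_mean, 15), 40)
  wq <- gh$w / sqrt(pi)

  fl <- cohort_fields()
  bins <- expand.grid(rep(list(c(0, 1)), length(fl$binary)))
  names(bins) <- fl$binary
  cells <- merge(bins, data.frame(stage = c("I", "II", "III")))
  p_bin <- apply(cells[fl$binary], 1L, function(r) {
    prod(ifelse(r == 1, spec$binary_rates, 1 - spec$binary_rates))
  })
  p_cell <- p_bin * spec$stage_probs[cells$stage]

  beta <- spec$outcome
  bc <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  z <- (age - spec$age_mean) / spec$age_sd
  psi <- function(a) {
    # continuous part on the quadrature grid, per exposure level
    lp_age <- bc("age") * age + bc("age_std_sq") * z^2 +
      bc("exposure_age_std") * a * z
    lp_bmi <- bc("BMI") * bmi
    total <- 0
    for (i in seq_len(nrow(cells))) {
      const <- bc("(Intercept)") + bc("exposure") * a +
        sum(vapply(fl$binary, bc, 0) * cells[i, fl$binary]) +
        (if (cells$stage[i] == "II") bc("stage_II") else 0) +
        (if (cells$stage[i] == "III") bc("stage_III") else 0)
      grid <- outer(lp_age, lp_bmi, `+`) + const
      total <- total + p_cell[i] * sum(outer(wq, wq) * plogis(grid))
    }
    total
  }
  psi1 <- psi(1); psi0 <- psi(0)
  list(psi1 = psi1, psi0 = psi0, or = oracle_or(psi1, psi0))
}

# empirical EIC-targeting check
targeting_ok <- function(tmle_out, tol = 1e-8) {
  abs(mean(tmle_out$eic1)) <= tol * sd(tmle_out$eic1) &&
    abs(mean(tmle_out$eic0)) <= tol * sd(tmle_out$eic0)
}
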