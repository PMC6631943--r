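# Shared fixtures and independent oracles used across the test files.

ref_fdiss <- function() {
  fdiss_params(imax = 0.992, t_get = 0.73, hill_stomach = 16.7,
               diss_max = 0.115, t_itt = 2.18, t_ctt = 4.1,
               hill_intestine = 13.1)
}

# Scalar evaluation of the dissolved-fraction sum, written directly from
# the defining algebra (independent of the package's vectorised path).
fdiss_scalar <- function(t, imax = 0.992, t_get = 0.73, hs = 16.7,
                         dmax = 0.115, t_itt = 2.18, t_ctt = 4.1,
                         hi = 13.1) {
  t1 <- t_get + t_itt; t2 <- t_get + t_itt + t_ctt
  up <- function(tt, t50, h) if (tt <= 0) 0 else tt^h / (t50^h + tt^h)
  1 - imax * up(t, t_get, hs) +
    dmax * up(t, t1, hi) * (1 - up(t, t2, hi))
}

# Implicit closed form of Michaelis-Menten depletion: time at which the
# undissolved fraction equals x (x0 = 1).
mm_time_oracle <- function(vmax, am50, x) (am50 * log(1 / x) + (1 - x)) / vmax

# Matrix exponential via eigendecomposition (the test systems below are
# diagonalisable with distinct eigenvalues).
expm_eigen <- function(A, t) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values * t), nrow(A)) %*% solve(e$vectors))
}

# Analytic concentration for the fully linear release chain:
# tablet -(k_rel)-> lumen -(k_lag)-> gut -(k_a)-> central <-> peripheral,
# elimination from central. Returns ng/mL for states in fraction-of-dose.
linear_chain_conc <- function(times, k_rel, k_lag, k_a, v1, v2, cl, cld,
                              dose) {
  A <- rbind(
    c(-k_rel, 0, 0, 0, 0),
    c(k_rel, -k_lag, 0, 0, 0),
    c(0, k_lag, -k_a, 0, 0),
    c(0, 0, k_a, -(cl + cld) / v1, cld / v2),
    c(0, 0, 0, cld / v1, -cld / v2))
  x0 <- c(1, 0, 0, 0, 0)
  vapply(times, function(t) {
    x <- expm_eigen(A, t) %*% x0
    x[4] * dose / v1 * 1000
  }, numeric(1))
}

subject_parm_vector_test <- pkivivc:::subject_parm_vector
with_seed_test <- pkivivc:::with_seed

# Small two-formulation design for quick estimation tests.
small_design <- function(n_subjects = 2) {
  study_design(
    formulations = data.frame(formulation_id = c("IR", "SR_medium"),
                              dose_mg = c(20, 60),
                              stringsAsFactors = FALSE),
    n_subjects = n_subjects)
}

# Population model restricted to the two formulations of small_design().
small_popk_model <- function(sigma = 0.15) {
  full <- sildenafil_popk_model(sigma = sigma)
  keep <- !grepl("^vmax_invivo:(SR_fast|SR_slow)$", names(full$theta))
  popk_model(theta = full$theta[keep], omega2 = full$omega2[keep],
             sigma = sigma,
             formulations = full$formulations[
               full$formulations$formulation_id %in% c("IR", "SR_medium"), ])
}
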