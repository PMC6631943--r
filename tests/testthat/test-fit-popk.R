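make_subject_data <- function(model, fid, eta = NULL, times = NULL,
                              sid = "s1") {
  if (is.null(times))
    times <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)
  sp <- pkivivc:::subject_from_model(model, fid, eta = eta,
                                     subject_id = sid)
  prof <- simulate_pk(sp, times)
  data.frame(subject_id = sid, formulation_id = fid, dose_mg = sp$dose,
             time_h = times, conc_ng_ml = prof$conc_ng_ml,
             stringsAsFactors = FALSE)
}

test_that("the conditional mode collapses to the population means as variability vanishes", {
  m <- small_popk_model()
  m$omega2[] <- 0
  d <- make_subject_data(m, "IR")
  cm <- conditional_mode(d, m)
  expect_true(all(cm$eta == 0))
  typ <- typical_subject(m, "IR")
  expect_equal(subject_parm_vector_test(cm$subject),
               subject_parm_vector_test(typ), tolerance = 1e-12)
  expect_error(conditional_mode(d[0, ], m), "no quantifiable")
})

test_that("the conditional mode recovers known individual deviations from near-noiseless data", {
  m <- small_popk_model(sigma = 0.01)
  m$omega2[] <- 0
  m$omega2[c("cl", "vmax_invivo:SR_medium")] <- 0.3
  eta_true <- c("cl" = 0.25, "vmax_invivo:SR_medium" = -0.2)
  d <- make_subject_data(m, "SR_medium", eta = eta_true)
  cm <- conditional_mode(d, m)
  expect_equal(cm$eta[["cl"]], 0.25, tolerance = 0.01)
  expect_equal(cm$eta[["vmax_invivo:SR_medium"]], -0.2, tolerance = 0.02)
  # dimensions without variability stay pinned at the population mean
  expect_identical(cm$eta[["v1"]], 0)
})

test_that("population fits are bitwise deterministic given the seed", {
  truth <- small_popk_model(sigma = 0.12)
  coh <- generate_cohort(truth, small_design(), seed = 31)
  ctrl <- popk_control(n_samples = 30, max_iter = 3, seed = 17,
                       mode_maxit = 30)
  f1 <- suppressWarnings(fit_popk(coh$data, truth, ctrl))
  f2 <- suppressWarnings(fit_popk(coh$data, truth, ctrl))
  expect_identical(f1$theta_path, f2$theta_path)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("fully censored subjects are excluded with a warning and the fit proceeds", {
  truth <- small_popk_model(sigma = 0.1)
  coh <- generate_cohort(truth, small_design(), seed = 6)
  dat <- coh$data
  dat$conc_ng_ml[dat$subject_id == "IR_01"] <- 1   # all below LLOQ
  dat$blq[dat$subject_id == "IR_01"] <- TRUE
  w <- capture_warnings(
    fit <- fit_popk(dat, truth,
                    popk_control(n_samples = 20, max_iter = 2, seed = 2,
                                 mode_maxit = 15, tol_window = 1)))
  expect_true(any(grepl("IR_01 excluded", w)))
  expect_identical(fit$n_subjects, 3L)
})

test_that("stopping before convergence is flagged, not silent", {
  truth <- small_popk_model(sigma = 0.1)
  coh <- generate_cohort(truth, small_design(), seed = 9)
  expect_warning(
    fit <- fit_popk(coh$data, truth,
                    popk_control(n_samples = 20, max_iter = 2, seed = 3,
                                 mode_maxit = 15)),
    "convergence criterion")
  expect_false(fit$converged)
})

test_that("the importance-sampled log-likelihood does not decrease beyond Monte Carlo error", {
  # fixture with variability on a well-dimensioned subset (5 random
  # effects against 10+ observations per subject keeps the conditional
  # densities well behaved)
  truth <- small_popk_model(sigma = 0.15)
  truth$omega2[] <- 0
  truth$omega2[c("cl", "v1", "k_a", "vmax_invivo:IR",
                 "vmax_invivo:SR_medium")] <- c(0.1, 0.1, 0.2, 0.2, 0.2)
  coh <- generate_cohort(truth, small_design(n_subjects = 3), seed = 14)
  fit <- suppressWarnings(fit_popk(
    coh$data, truth,
    popk_control(n_samples = 150, max_iter = 8, seed = 5)))
  ll <- fit$loglik; se <- fit$loglik_se
  drops <- diff(ll)
  allowance <- 3 * sqrt(se[-length(se)]^2 + se[-1]^2)
  expect_true(all(drops > -pmax(allowance, 1e-8)))
})

test_that("visual predictive check bands behave as designed", {
  m <- small_popk_model()
  m0 <- m; m0$omega2[] <- 0; m0$sigma <- 0
  v0 <- visual_predictive_check(m0, small_design(), n_sim = 100, seed = 1)
  expect_equal(v0$p5, v0$typical, tolerance = 1e-9)
  expect_equal(v0$p95, v0$typical, tolerance = 1e-9)
  expect_identical(v0$p50[v0$time_h == 0], rep(0, 2))

  m_wide <- m; m_wide$omega2 <- m$omega2 * 2
  v1 <- visual_predictive_check(m, small_design(), n_sim = 150, seed = 2)
  v2 <- visual_predictive_check(m_wide, small_design(), n_sim = 150,
                                seed = 2)
  at <- v1$formulation_id == "IR" & v1$time_h == 2
  expect_gt(v2$p95[at] - v2$p5[at], v1$p95[at] - v1$p5[at])
  expect_error(visual_predictive_check(m, small_design(), n_sim = 10),
               "n_sim")
})
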