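test_that("lambda_z is exact on a mono-exponential profile", {
  tt <- c(4, 6, 8, 12, 24)
  lz <- compute_lambda_z(tt, 100 * exp(-0.2 * tt))
  expect_equal(lz$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(lz$t_half, log(2) / 0.2, tolerance = 1e-10)
  expect_gte(lz$n_points, 3)
})

test_that("lambda_z matches the disposition eigenvalue on a two-compartment profile", {
  # bolus into the central compartment; eigenvalue oracle from the
  # rate matrix
  v1 <- 22; v2 <- 31; cl <- 9.97; cld <- 49.2
  A <- rbind(c(-(cl + cld) / v1, cld / v2), c(cld / v1, -cld / v2))
  lam <- sort(-eigen(A)$values)   # positive rates, ascending
  t_half_z <- log(2) / lam[1]
  tt <- c(0.25, 0.5, 1, 2, 4, seq(6, ceiling(4 * t_half_z), by = 2))
  conc <- vapply(tt, function(t) (expm_eigen(A, t) %*% c(20, 0))[1] / v1,
                 numeric(1)) * 1000
  lz <- compute_lambda_z(tt, conc)
  expect_equal(lz$lambda_z, lam[1], tolerance = 0.02)
})

test_that("lambda_z rejects unusable profiles", {
  expect_error(compute_lambda_z(c(1, 2, 3), c(0, 0, 0)), "quantifiable")
  expect_error(compute_lambda_z(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "after Tmax")
  expect_error(compute_lambda_z(c(1, 2, 3, 4, 5), c(100, 1, 2, 3, 4)),
               "declining")
  expect_error(compute_lambda_z(c(1, 2, 3), c(5, 4, 3)), "after Tmax")
})

test_that("AUC follows the trapezoid on a triangular profile and the analytic value on an exponential", {
  tri <- compute_nca(c(0, 1, 2, 3, 4, 5), c(0, 100, 0.01, 0.005, 0.0025,
                                            0.00125), dose = 1)
  expect_equal(tri$auc_all, 100, tolerance = 2e-3)

  tt <- c(0, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48)
  # log-down segments are exact on a mono-exponential decline
  nca <- compute_nca(tt, 100 * exp(-0.2 * tt), dose = 1,
                     auc_method = "linear_log")
  expect_equal(nca$auc_inf, 500, tolerance = 1e-8)     # C0/lambda
  expect_equal(nca$lambda_z, 0.2, tolerance = 1e-8)
  # CL/F in mL/min: dose[mg]*1e6 / AUCinf[ng.h/mL] / 60
  expect_equal(nca$cl_f, 1e6 / nca$auc_inf / 60, tolerance = 1e-10)
  # Vz/F consistency: CL/F converted to L/h over lambda_z
  expect_equal(nca$vz_f, (nca$cl_f * 60 / 1000) / nca$lambda_z,
               tolerance = 1e-10)
  expect_equal(nca$t_half, log(2) / nca$lambda_z, tolerance = 1e-12)
  expect_gte(nca$auc_inf, nca$auc_all)
})

test_that("trapezoidal AUC tracks the analytic integral on the study sampling schedule", {
  tt <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 12,
          24, 36, 48)
  for (lam in c(0.1, 0.2, 0.5)) {
    truth <- 100 / lam * (1 - exp(-lam * 48))
    # linear-up/log-down is exact on the decline
    ll <- compute_nca(tt, 100 * exp(-lam * tt), dose = 1,
                      auc_method = "linear_log")
    expect_equal(ll$auc_all, truth, tolerance = 1e-8)
    # the plain linear rule overestimates by the convexity bias of the
    # sparse late samples, bounded here
    lin <- compute_nca(tt, 100 * exp(-lam * tt), dose = 1)
    expect_gte(lin$auc_all, truth)
    expect_lt(lin$auc_all / truth - 1, 0.08)
  }
})

test_that("relative bioavailability is the dose-normalised AUC ratio and is scale-invariant", {
  tt <- c(0, 0.5, 1, 2, 4, 8, 12, 24)
  ref <- compute_nca(tt, 100 * exp(-0.2 * tt), dose = 10)
  tst <- compute_nca(tt, 50 * exp(-0.2 * tt), dose = 5)
  r1 <- compute_nca(tt, 50 * exp(-0.2 * tt), dose = 5, reference = ref)
  expect_equal(r1$relative_ba, 100, tolerance = 1e-8)
  # rescaling both doses by a common factor leaves the ratio unchanged
  ref2 <- compute_nca(tt, 100 * exp(-0.2 * tt), dose = 30)
  r2 <- compute_nca(tt, 50 * exp(-0.2 * tt), dose = 15, reference = ref2)
  expect_equal(r2$relative_ba, r1$relative_ba, tolerance = 1e-8)
})

test_that("high extrapolation is flagged and BLQ handling follows the stated policy", {
  tt <- c(1, 2, 3, 4, 5)
  expect_warning(
    nca <- compute_nca(tt, 100 * exp(-0.05 * tt), dose = 1),
    "extrapolation")
  expect_true(nca$high_extrapolation)
  # leading BLQ points enter the AUC as zeros
  tt2 <- c(0.25, 0.5, 1, 2, 4, 6, 8)
  conc <- c(1, 2, 120, 90, 50, 25, 12)
  blq <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  nca2 <- compute_nca(tt2, conc, dose = 1, blq = blq)
  manual <- sum(diff(tt2) *
    (head(c(0, 0, 120, 90, 50, 25, 12), -1) +
     tail(c(0, 0, 120, 90, 50, 25, 12), -1)) / 2)
  expect_equal(nca2$auc_all, manual, tolerance = 1e-10)
})

test_that("the cohort NCA table mirrors the per-subject metrics with summary rows", {
  pop <- sildenafil_popk_model(sigma = 0.1)
  coh <- generate_cohort(pop, small_design(), seed = 5)
  tab <- nca_table(coh$data, reference_formulation = "IR")
  subj <- tab[tab$row == "subject", ]
  expect_identical(nrow(subj), 4L)
  expect_true(all(c("mean", "sd") %in% tab$row))
  m_ir <- tab[tab$row == "mean" & tab$formulation_id == "IR", "cmax"]
  expect_equal(m_ir, mean(subj$cmax[subj$formulation_id == "IR"]),
               tolerance = 1e-12)
  expect_true(all(is.na(subj$relative_ba) | subj$relative_ba > 0))
  # typical IR profile peaks within 1.5 h
  ir_typ <- simulate_pk(typical_subject(pop, "IR"), seq(0, 48, 0.25))
  nca_ir <- compute_nca(ir_typ$time_h, ir_typ$conc_ng_ml, dose = 20)
  expect_lt(nca_ir$tmax, 1.5)
})
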