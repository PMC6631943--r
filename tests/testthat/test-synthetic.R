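test_that("individual draws follow the exponential variability model", {
  pop <- sildenafil_popk_model()
  # zero variability: the individual equals the population means
  pop0 <- pop; pop0$omega2[] <- 0
  sp <- sample_individual(pop0, "IR", seed = 1)
  typ <- typical_subject(pop0, "IR")
  expect_equal(subject_parm_vector_test(sp), subject_parm_vector_test(typ),
               tolerance = 1e-12)
  # lognormal identities on many draws: median = theta,
  # mean(exp(eta)) = exp(omega2/2)
  pop1 <- pop; pop1$omega2[] <- 0.25
  v1 <- with_seed_test(99, vapply(1:10000, function(i)
    sample_individual(pop1, "IR", subject_id = i)$disposition$v1,
    numeric(1)))
  expect_equal(median(v1), pop$theta[["v1"]], tolerance = 0.02)
  expect_equal(mean(v1 / pop$theta[["v1"]]), exp(0.125), tolerance = 0.03)
})

test_that("cohorts are pure functions of their seed and noiseless at zero variability", {
  pop <- sildenafil_popk_model(sigma = 0.15)
  c1 <- generate_cohort(pop, small_design(), seed = 123)
  c2 <- generate_cohort(pop, small_design(), seed = 123)
  expect_identical(c1$data, c2$data)
  c3 <- generate_cohort(pop, small_design(), seed = 124)
  expect_false(identical(c1$data, c3$data))

  pop0 <- sildenafil_popk_model(sigma = 1e-12)
  pop0$omega2[] <- 0
  c0 <- generate_cohort(pop0, small_design(), seed = 1)
  for (fid in c("IR", "SR_medium")) {
    d <- c0$data[c0$data$subject_id == paste0(fid, "_01"), ]
    typ <- simulate_pk(typical_subject(pop0, fid), d$time_h)
    expect_equal(d$conc_ng_ml, typ$conc_ng_ml, tolerance = 1e-6)
  }
})

test_that("censoring below the LLOQ grows as the dose shrinks", {
  pop <- sildenafil_popk_model(sigma = 0.1)
  des_hi <- study_design(formulations = data.frame(
    formulation_id = "SR_medium", dose_mg = 60), n_subjects = 4)
  des_lo <- study_design(formulations = data.frame(
    formulation_id = "SR_medium", dose_mg = 20), n_subjects = 4)
  blq_hi <- mean(generate_cohort(pop, des_hi, seed = 5)$data$blq)
  blq_lo <- mean(generate_cohort(pop, des_lo, seed = 5)$data$blq)
  expect_gt(blq_lo, blq_hi)
})

test_that("generated dissolution vessels share the closed-form mean curve", {
  p <- invitro_release_params(0.124, 0.395)
  d0 <- generate_invitro_dataset(p, study_design(), "SR_slow",
                                 noise_sd = 0, seed = 1)
  ref <- 100 * solve_invitro_dissolution(p, study_design()$dissolution_times)
  for (v in unique(d0$vessel_id))
    expect_equal(d0$pct_dissolved[d0$vessel_id == v], ref,
                 tolerance = 1e-10)
  # final point agrees with the implicit-form oracle: inverting the
  # last dissolved fraction must give back the 24 h sampling time
  x_last <- 1 - ref[length(ref)] / 100
  expect_equal(mm_time_oracle(0.124, 0.395, x_last), 24,
               tolerance = 1e-6)
  # with noise, vessels differ from each other but only by noise scale
  d1 <- generate_invitro_dataset(p, study_design(), "SR_slow",
                                 noise_sd = 2, seed = 1)
  spread <- tapply(d1$pct_dissolved, d1$time_h, sd)
  expect_true(all(spread < 10))
  expect_gt(max(spread), 0)
})

test_that("generated data stay within physical ranges", {
  pop <- sildenafil_popk_model(sigma = 0.3)
  coh <- generate_cohort(pop, small_design(n_subjects = 3), seed = 8)
  expect_true(all(coh$data$conc_ng_ml >= 0))
  expect_identical(coh$data$blq, coh$data$conc_ng_ml < 5)
  d <- generate_invitro_dataset(invitro_release_params(6.58, 0.395),
                                study_design(), "IR", noise_sd = 5,
                                seed = 2)
  expect_true(all(d$pct_dissolved >= 0 & d$pct_dissolved <= 105))
})
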