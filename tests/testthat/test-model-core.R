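test_that("the ODE right-hand side conserves mass and vanishes at the zero state", {
  pop <- sildenafil_popk_model()
  sp <- typical_subject(pop, "SR_medium")
  zero <- c(x_tablet = 0, x_lumen = 0, x_gut = 0, x1 = 0, x2 = 0,
            x_elim = 0)
  expect_true(all(ode_rhs(zero, 1, sp) == 0))
  set.seed(21)
  for (i in 1:10) {
    st <- c(x_tablet = runif(1), x_lumen = runif(1), x_gut = runif(1),
            x1 = runif(1, 0, 20), x2 = runif(1, 0, 20),
            x_elim = runif(1, 0, 20))
    d <- ode_rhs(st, runif(1, 0, 24), sp)
    # fraction-scaled derivative sum is zero: nothing enters or leaves
    bal <- d[["x_tablet"]] + d[["x_lumen"]] + d[["x_gut"]] +
      (d[["x1"]] + d[["x2"]] + d[["x_elim"]]) / sp$dose
    expect_lt(abs(bal), 1e-12)
  }
})

test_that("simulated trajectories conserve mass and dissolve monotonically", {
  pop <- sildenafil_popk_model()
  tt <- seq(0, 48, by = 0.25)
  for (seed in 1:5) {
    sp <- sample_individual(pop, sample(pop$formulations$formulation_id, 1),
                            seed = seed, subject_id = "prop")
    prof <- simulate_pk(sp, tt, keep_states = TRUE)
    st <- attr(prof, "states")
    total <- st[, "x_tablet"] + st[, "x_lumen"] + st[, "x_gut"] +
      (st[, "x1"] + st[, "x2"] + st[, "x_elim"]) / sp$dose
    expect_lt(max(abs(total - 1)), 1e-6)
    expect_true(all(diff(st[, "x_tablet"]) <= 1e-9))
    expect_true(all(prof$conc_ng_ml >= -1e-9))
  }
})

test_that("concentration at dose time is zero and scales exactly with dose", {
  pop <- sildenafil_popk_model()
  tt <- c(0, 0.5, 1, 2, 4, 8, 24)
  sp1 <- typical_subject(pop, "IR", dose = 20)
  sp2 <- typical_subject(pop, "IR", dose = 40)
  p1 <- simulate_pk(sp1, tt); p2 <- simulate_pk(sp2, tt)
  expect_identical(p1$conc_ng_ml[1], 0)
  expect_equal(p2$conc_ng_ml[-1] / p1$conc_ng_ml[-1], rep(2, 6),
               tolerance = 1e-7)
})

test_that("with a saturating AM50 and flat dissolved fraction the model reduces to a linear chain", {
  # vmax/am50 ratio fixes a first-order release rate; imax ~ 0 and
  # diss_max = 0 make F_Diss identically 1; the whole system is then
  # linear and has a matrix-exponential solution
  k_rel <- 2
  sp <- subject_params(
    f_diss = fdiss_params(imax = 1e-12, t_get = 0.73, hill_stomach = 16.7,
                          diss_max = 0, t_itt = 2.18, t_ctt = 4.1,
                          hill_intestine = 13.1),
    dissolution = invivo_release_params(vmax = k_rel * 1e6, am50 = 1e6),
    disposition = disposition_params(k_lag = 3.13, k_a = 4.37, v1 = 22,
                                     v2 = 31, cl = 9.97, cld = 49.2),
    dose = 20)
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  sim <- simulate_pk(sp, tt)$conc_ng_ml
  oracle <- linear_chain_conc(tt, k_rel, 3.13, 4.37, 22, 31, 9.97, 49.2, 20)
  expect_equal(sim, oracle, tolerance = 1e-5)
})

test_that("compiled and pure-R engines integrate to the same solution", {
  pop <- sildenafil_popk_model()
  tt <- c(0.25, 1, 2, 4, 8, 12, 24, 48)
  for (fid in c("IR", "SR_slow")) {
    sp <- typical_subject(pop, fid)
    a <- simulate_pk(sp, tt, engine = "compiled")$conc_ng_ml
    b <- simulate_pk(sp, tt, engine = "r")$conc_ng_ml
    expect_equal(a, b, tolerance = 1e-7)
  }
})

test_that("in vivo dissolved percentage starts at zero and is non-decreasing", {
  pop <- sildenafil_popk_model()
  sp <- typical_subject(pop, "SR_medium")
  expect_identical(in_vivo_dissolved_pct(sp, 0), 0)
  v <- in_vivo_dissolved_pct(sp, c(1, 2, 4, 8, 12, 24, 48))
  expect_true(all(diff(v) >= -1e-9))
  expect_true(all(v >= 0 & v <= 100))
})

test_that("profiles peak early, and slow tablets show a colonic second peak", {
  pop <- sildenafil_popk_model()
  g <- seq(0, 12, by = 0.01)
  prof_ir <- simulate_pk(typical_subject(pop, "IR"), g)
  expect_lt(prof_ir$time_h[which.max(prof_ir$conc_ng_ml)], 1.5)
  # colonic re-dissolution produces a genuine second peak for the
  # slower tablets (a shoulder at most for the immediate release)
  for (fid in c("SR_medium", "SR_slow")) {
    prof <- simulate_pk(typical_subject(pop, fid), g)
    w <- prof$conc_ng_ml[g >= 3 & g <= 10]
    expect_true(any(diff(sign(diff(w))) == -2))  # interior local maximum
  }
})
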