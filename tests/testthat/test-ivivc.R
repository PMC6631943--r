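published_pairs <- function() {
  list(x = c(IR = 6.58, SR_fast = 1.40, SR_medium = 0.358,
             SR_slow = 0.124),
       y = c(IR = 4.42, SR_fast = 1.71, SR_medium = 0.781,
             SR_slow = 0.219))
}

test_that("the power law is recovered exactly from noise-free pairs", {
  x <- c(0.1, 0.5, 1, 2, 6)
  y <- 2 * sqrt(x)
  for (w in c("log", "none")) {
    f <- fit_power_ivivc(x, y, weighting = w)
    expect_equal(unname(coef(f)), c(2, 0.5, 0), tolerance = 1e-6)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
})

test_that("the published release-rate pairs reproduce the published correlation", {
  p <- published_pairs()
  f <- fit_power_ivivc(p$x, p$y)
  expect_equal(f$a, 2.1411, tolerance = 0.02)
  expect_equal(f$b, 0.4388, tolerance = 0.02)
  expect_equal(f$c, -0.6346, tolerance = 0.05)
  expect_gt(f$r2, 0.99)
  # returned optimum is at least as good as every multi-start origin
  expect_true(all(f$objective <= f$start_objectives + 1e-9))
})

test_that("rate conversion reproduces direct evaluations and preserves formulation order", {
  p <- published_pairs()
  f <- fit_power_ivivc(p$x, p$y)
  expect_equal(convert_vmax(f, 6.58), 4.26, tolerance = 0.02)
  expect_equal(convert_vmax(f, 0.124), 0.222, tolerance = 0.02)
  conv <- convert_vmax(f, sort(unname(p$x)))
  expect_true(all(diff(conv) > 0))   # monotone in the in vitro rate
  # identity model passes through
  id <- fit_power_ivivc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(convert_vmax(id, 1.7), 1.7, tolerance = 1e-5)
  expect_warning(convert_vmax(f, 100), "extrapolating")
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(fit_power_ivivc(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_ivivc(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("percentage prediction error follows its definition and scale invariance", {
  expect_identical(percent_pe(366.5, 338.7), 7.6)
  expect_identical(percent_pe(124.9, 137.2), 9.8)
  expect_identical(percent_pe(5, 5), 0)
  expect_error(percent_pe(0, 1), "positive")
  set.seed(3)
  o <- runif(5, 10, 100); p <- o * runif(5, 0.7, 1.3)
  expect_identical(percent_pe(3.7 * o, 3.7 * p), percent_pe(o, p))
})

test_that("the validation report reproduces the published prediction errors", {
  obs <- sildenafil_observed_exposure()
  pred <- data.frame(
    formulation_id = obs$formulation_id,
    cmax = c(338.7, 797.4, 439.9, 137.2),
    auc_all = c(1942.2, 5609.2, 3896.7, 1010.0))
  rep <- ivivc_validate(obs, pred)
  expect_equal(rep$table$cmax_pe, c(7.6, 4.0, 7.2, 9.8))
  expect_equal(rep$table$auc_pe, c(1.5, 4.7, 7.7, 0.1))
  expect_equal(rep$summary$mean_pe[1], 7.2, tolerance = 0.06)
  expect_equal(rep$summary$mean_pe[2], 3.5, tolerance = 0.05)
  expect_equal(rep$summary$sd_pe[2], 3.4, tolerance = 0.05)
  expect_true(rep$pass)
  # identical observed and predicted values: zero error, pass
  rep0 <- ivivc_validate(obs, obs)
  expect_true(all(rep0$table$cmax_pe == 0) && rep0$pass)
  expect_error(ivivc_validate(obs, pred[-1, ]), "differ")
})

test_that("Monte Carlo prediction is deterministic given its seed and collapses without variability", {
  pop <- small_popk_model()
  p <- published_pairs()
  f <- fit_power_ivivc(p$x, p$y)
  iv <- invitro_release_params(6.58, 0.395)
  pop0 <- pop; pop0$omega2[] <- 0; pop0$sigma <- 0
  mc0 <- predict_from_invitro(f, pop0, iv, "IR", mode = "monte_carlo",
                              n = 100, seed = 4)
  typ <- predict_from_invitro(f, pop0, iv, "IR", mode = "typical")
  expect_equal(mc0$cmax, typ$cmax, tolerance = 1e-9)
  expect_lt(max(abs(mc0$bands$p95 - mc0$bands$p5)), 1e-9)
  mc1 <- predict_from_invitro(f, pop, iv, "IR", mode = "monte_carlo",
                              n = 100, seed = 11)
  mc2 <- predict_from_invitro(f, pop, iv, "IR", mode = "monte_carlo",
                              n = 100, seed = 11)
  expect_identical(mc1$cmax_individual, mc2$cmax_individual)
})

test_that("leaving one formulation out still predicts its peak exposure within 15%", {
  # synthetic truth: typical profiles of the full published model
  pop <- sildenafil_popk_model()
  p <- published_pairs()
  grid <- seq(0, 48, by = 0.01)
  for (held in c("IR", "SR_fast")) {
    keep <- setdiff(names(p$x), held)
    f3 <- fit_power_ivivc(p$x[keep], p$y[keep])
    obs_cmax <- max(simulate_pk(typical_subject(pop, held), grid)$conc_ng_ml)
    pred <- suppressWarnings(predict_from_invitro(
      f3, pop, invitro_release_params(p$x[[held]], 0.395), held,
      mode = "typical"))
    expect_lt(percent_pe(obs_cmax, pred$cmax), 15)
  }
})
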