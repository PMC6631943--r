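test_that("dissolved-fraction components match their defining algebra", {
  p <- ref_fdiss()
  # continuous extension at t = 0
  expect_identical(f_diss_stomach(0, p), 1)
  expect_identical(f_diss_intestine(0, p), 0)
  expect_identical(f_diss_total(0, p), 1)
  # half-maximal gastric decrease at t = t_get by construction
  expect_equal(f_diss_stomach(0.73, p), 1 - 0.992 / 2, tolerance = 1e-12)
  # long-time limits
  expect_equal(f_diss_stomach(100, p), 1 - 0.992, tolerance = 1e-6)
  expect_lt(f_diss_intestine(1000, p), 1e-6)
  # scalar oracle across a grid (independent re-derivation)
  for (t in c(0.1, 0.5, 0.73, 1, 2, 2.91, 4, 6.3, 8, 12, 30))
    expect_equal(f_diss_total(t, p), fdiss_scalar(t), tolerance = 1e-12)
  # direct evaluation near the intestinal peak
  expect_equal(f_diss_intestine(4, p), 0.113, tolerance = 0.01)
})

test_that("dissolved-fraction components respect their bounds everywhere", {
  set.seed(11)
  for (i in 1:20) {
    p <- fdiss_params(imax = runif(1, 0.1, 1), t_get = runif(1, 0.2, 3),
                      hill_stomach = runif(1, 1, 30),
                      diss_max = runif(1, 0, 0.5),
                      t_itt = runif(1, 0.5, 5), t_ctt = runif(1, 1, 10),
                      hill_intestine = runif(1, 1, 30))
    tt <- c(0, sort(runif(50, 0, 60)))
    fs <- f_diss_stomach(tt, p); fi <- f_diss_intestine(tt, p)
    expect_true(all(fs >= 1 - p$imax - 1e-12 & fs <= 1 + 1e-12))
    expect_true(all(fi >= -1e-12 & fi <= p$diss_max + 1e-12))
    expect_true(all(diff(fs) <= 1e-12))  # gastric component decreases
  }
})

test_that("invalid dissolved-fraction inputs are rejected", {
  p <- ref_fdiss()
  expect_error(f_diss_total(-0.1, p), "non-negative")
  expect_error(fdiss_params(imax = 1.2, t_get = 0.7, hill_stomach = 16,
                            diss_max = 0.1, t_itt = 2, t_ctt = 4,
                            hill_intestine = 13), "imax")
  expect_error(fdiss_params(imax = 0.9, t_get = -1, hill_stomach = 16,
                            diss_max = 0.1, t_itt = 2, t_ctt = 4,
                            hill_intestine = 13), "t_get")
})

test_that("transit landmarks are ordered and the profile summary finds the colonic window", {
  p <- ref_fdiss()
  expect_lt(p$t_get, p$t_trans1)
  expect_lt(p$t_trans1, p$t_trans2)
  s <- fdiss_profile_summary(p)
  expect_lt(s$minimum, 0.01)
  expect_gt(s$window_start, s$t_minimum)
  expect_gt(s$window_end, s$window_start)
})
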