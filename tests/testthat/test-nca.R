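test_that("trapezoid AUC handles rectangles, exponentials and edges", {
  expect_equal(auc_trapezoid(0:10, rep(1, 11), 10), 10)
  t <- seq(0, 10, by = 0.01)
  expect_equal(auc_trapezoid(t, exp(-t), 10), 1 - exp(-10), tolerance = 1e-4)
  expect_equal(auc_trapezoid(0:10, rep(1, 11), 0), 0)
  # partial step interpolation
  expect_equal(auc_trapezoid(c(0, 1, 2), c(1, 1, 1), 1.5), 1.5)
  expect_error(auc_trapezoid(0:10, rep(1, 11), 11), "outside")
})

test_that("terminal slope fit is exact on a mono-exponential", {
  t <- seq(0, 72, by = 0.5)
  fit <- lambda_z_fit(t, 100 * exp(-0.05 * t))
  expect_equal(fit$lambda_z, 0.05, tolerance = 1e-10)
  expect_equal(fit$t_half, log(2) / 0.05, tolerance = 1e-10)
  expect_error(lambda_z_fit(c(0, 1), c(2, 1), window = c(0, 1)), "3 points")
  expect_error(lambda_z_fit(t, c(-1, rep(1, length(t) - 1)),
                            window = c(0, 72)), "non-positive")
})

test_that("bi-exponential fit recovers known phases exactly", {
  t <- default_time_grid()
  y <- 370 * exp(-1.4441 * t) + 180 * exp(-0.0431 * t)
  fit <- biexp_fit(t, y)
  expect_equal(fit$alpha, 1.4441, tolerance = 1e-6)
  expect_equal(fit$beta, 0.0431, tolerance = 1e-6)
  expect_equal(fit$A, 370, tolerance = 1e-6)
  expect_equal(fit$B, 180, tolerance = 1e-6)
})

test_that("bi-exponential fit flags degenerate mono-exponential input", {
  t <- default_time_grid()
  expect_error(biexp_fit(t, 100 * exp(-0.05 * t)), "degenerate")
  expect_error(biexp_fit(c(0, 1, 2), c(3, 2, 1)), "at least 6")
})

test_that("NCA recovers the generating model from the reference profile", {
  ref <- reference_subject()
  prof <- simulate_iv_bolus(ref, 30 * 74)
  nca <- nca_summary(prof, weight = 74)
  expect_equal(nca$cmax, prof$conc_plasma[1])  # bolus: Cmax at t = 0
  expect_equal(nca$tmax, 0)
  # dose/AUCinf recovers the true clearance within the grid bound
  expect_equal(nca$cl_obs, ref$cl_renal, tolerance = 0.005)
  expect_equal(nca$auc_inf, 2220 / 0.5, tolerance = 0.005)
  expect_gte(nca$auc_inf, nca$auc_last)
  # observed half-lives recover the structural ones
  expect_equal(nca$t_half_dist_obs, 0.48, tolerance = 1e-4)
  expect_equal(nca$t_half_elim_obs, log(2) / ref$beta, tolerance = 1e-4)
  expect_equal(nca$c_at_1h, 256.17, tolerance = 0.05)
  expect_equal(nca$fe_72, 0.958, tolerance = 0.005)
  expect_equal(nca$cl_per_kg, 0.5 / 74 * 1000, tolerance = 0.005)
})

test_that("NCA is model-blind: works from bare numeric profiles", {
  t <- seq(0, 72, by = 0.1)
  y <- 500 * exp(-0.1 * t)
  prof <- list(times = t, conc_plasma = y, urine_cum = NULL, dose = 1000)
  nca <- nca_summary(prof, weight = 70, fit_biexp = FALSE)
  expect_equal(nca$lambda_z, 0.1, tolerance = 1e-8)
  expect_equal(nca$cl_obs, 1000 / (500 / 0.1), tolerance = 1e-3)
  expect_true(is.na(nca$fe_72))
})
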