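test_that("default design enrols 100 subjects, half female, dose by weight", {
  st <- run_study(trial_design(), "healthy", fit_biexp = FALSE)
  s <- st$subjects
  expect_equal(nrow(s), 100)
  expect_equal(sum(s$sex == "F"), 50)
  expect_equal(unname(table(s$trial)), rep(10L, 10), ignore_attr = TRUE)
  # pooled mean dose is exactly 30 x pooled mean weight
  expect_equal(mean(s$dose), 30 * mean(s$weight), tolerance = 1e-12)
})

test_that("studies are bit-reproducible under the same seed", {
  d <- trial_design(n_trials = 3, n_subjects = 5, global_seed = 77)
  a <- run_study(d, "renal_sev", fit_biexp = FALSE)
  b <- run_study(d, "renal_sev", fit_biexp = FALSE)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$conc, b$conc)
  d2 <- trial_design(n_trials = 3, n_subjects = 5, global_seed = 78)
  c <- run_study(d2, "renal_sev", fit_biexp = FALSE)
  expect_false(identical(a$subjects$weight, c$subjects$weight))
})

test_that("percentile envelope brackets the mean and widens with q range", {
  st <- run_study(trial_design(n_trials = 2, n_subjects = 10),
                  "healthy", fit_biexp = FALSE)
  e <- st$envelope
  expect_true(all(e$low <= e$mean + 1e-12 & e$mean <= e$high + 1e-12))
  wide <- percentile_envelope(st$conc, 0, 1, times = st$times)
  expect_true(all(wide$low <= e$low + 1e-12))
  expect_true(all(wide$high >= e$high - 1e-12))
  # min/max envelope equals the column extremes
  expect_equal(wide$low, apply(st$conc, 1, min))
  expect_equal(wide$high, apply(st$conc, 1, max))
})

test_that("identical profiles give a collapsed envelope; mismatched grids fail", {
  ref <- reference_subject()
  p <- simulate_iv_bolus(ref, 2220)
  e <- percentile_envelope(list(p, p, p))
  expect_equal(e$low, e$mean)
  expect_equal(e$high, e$mean)
  q <- simulate_iv_bolus(ref, 2220, times = c(0, 1, 2))
  expect_error(percentile_envelope(list(p, q)), "grid mismatch")
})

test_that("standard error of the mean Cmax shrinks roughly as 1/sqrt(n)", {
  mean_cmax <- function(n, seed) {
    d <- trial_design(n_trials = 1, n_subjects = n, global_seed = seed)
    mean(run_study(d, "healthy", fit_biexp = FALSE)$subjects$cmax)
  }
  m10 <- vapply(1:24, function(s) mean_cmax(10, 1000 + s), 0)
  m90 <- vapply(1:24, function(s) mean_cmax(90, 2000 + s), 0)
  ratio <- sd(m10) / sd(m90)  # expectation: 3
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 5.5)
})

test_that("study summary pools over subjects and reports per-trial means", {
  st <- run_study(trial_design(n_trials = 4, n_subjects = 5), "obese",
                  fit_biexp = FALSE)
  sm <- summary(st)
  expect_equal(nrow(sm$by_trial), 4)
  pooled_cmax <- sm$pooled$mean[sm$pooled$parameter == "cmax"]
  expect_equal(pooled_cmax, mean(st$subjects$cmax))
  expect_equal(sm$pooled$n[1], 20)
})
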