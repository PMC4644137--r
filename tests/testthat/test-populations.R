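test_that("built-in cohorts carry the calibrated physiology", {
  specs <- builtin_cohorts()
  expect_setequal(names(specs),
                  c("healthy", "renal_mod", "renal_sev", "obese", "oncology",
                    "cirrhosis_a", "cirrhosis_b", "cirrhosis_c"))
  expect_equal(specs$healthy$gfr_mean, 108)
  expect_equal(specs$healthy$albumin_mean, 45)
  expect_equal(specs$renal_mod$gfr_bounds, c(30, 60))
  # cirrhosis volume expansion and albumin both track severity
  v <- vapply(specs[c("cirrhosis_a", "cirrhosis_b", "cirrhosis_c")],
              `[[`, 0, "v_scale")
  expect_true(all(diff(v) > 0))
  alb <- vapply(specs[c("cirrhosis_a", "cirrhosis_b", "cirrhosis_c")],
                `[[`, 0, "albumin_mean")
  expect_true(all(diff(alb) < 0))
  expect_error(get_cohort("nonexistent"), "unknown cohort")
})

test_that("sampling reproduces the cohort weight calibration", {
  # cohort mean weight is the published mean dose / 30 mg/kg
  specs <- builtin_cohorts()
  for (lab in c("healthy", "obese")) {
    pop <- sample_cohort(specs[[lab]], 4000, global_seed = 11)
    target <- c(healthy = 73.8, obese = 99.9)[[lab]]
    se <- sd(pop$weight) / sqrt(nrow(pop))
    expect_lt(abs(mean(pop$weight) - target), 3 * se + 0.01)
    expect_equal(mean(pop$sex == "F"), 0.5)
    # implied mean dose within 2% of the published cohort dose
    dose_target <- c(healthy = 2212.90, obese = 2997.52)[[lab]]
    expect_lt(abs(30 * mean(pop$weight) - dose_target) / dose_target, 0.02)
  }
})

test_that("GFR sampling respects truncation bounds", {
  pop <- sample_cohort(builtin_cohorts()$renal_mod, 2000, global_seed = 12)
  expect_true(all(pop$gfr >= 30 & pop$gfr <= 60))
  # realized mean sits where the clearance calibration needs it
  expect_equal(mean(pop$gfr), 55.7, tolerance = 0.02)
})

test_that("same seed gives the identical individual, different seeds differ", {
  spec <- builtin_cohorts()$healthy
  a <- sample_individual(spec, "F", seed = 42)
  b <- sample_individual(spec, "F", seed = 42)
  expect_identical(a, b)
  c <- sample_individual(spec, "F", seed = 43)
  expect_false(identical(a$weight, c$weight))
})

test_that("renal clearance scales linearly with GFR from the reference", {
  spec <- builtin_cohorts()$healthy
  cmp <- compound_params()
  ref <- sample_individual(spec, "M", seed = 1)
  ref$weight <- 74; ref$gfr <- 96; ref$v1_scale <- 1
  pk <- subject_pk_from_physiology(ref, cmp, spec)
  expect_equal(pk$cl_renal, 0.5)
  ref$gfr <- 48
  expect_equal(subject_pk_from_physiology(ref, cmp, spec)$cl_renal, 0.25)
  # across a sampled population, correlation(gfr, cl) is exactly 1
  pop <- sample_cohort(spec, 500, global_seed = 3, compound = cmp)
  expect_equal(cor(pop$gfr, pop$cl_renal), 1.0, tolerance = 1e-12)
})

test_that("physiology map produces the spec'd volumes and fu", {
  cmp <- compound_params()
  spec <- builtin_cohorts()$cirrhosis_b
  ind <- sample_individual(spec, "M", seed = 9)
  ind$v1_scale <- 1
  pk <- subject_pk_from_physiology(ind, cmp, spec)
  expect_equal(pk$v1, cmp$v1_per_kg * ind$weight * 1.55)
  expect_equal(pk$v2, (cmp$vss_per_kg - cmp$v1_per_kg) * ind$weight * 1.55)
  expect_equal(pk$fu, fraction_unbound(cmp$kd_albumin,
                                       albumin_g_per_l_to_um(ind$albumin)))
})

test_that("cohort sampling means match their specs within Monte-Carlo error", {
  for (lab in names(builtin_cohorts())) {
    spec <- builtin_cohorts()[[lab]]
    pop <- sample_cohort(spec, 3000, global_seed = 21)
    se_alb <- sd(pop$albumin) / sqrt(nrow(pop))
    expect_lt(abs(mean(pop$albumin) - spec$albumin_mean), 4 * se_alb)
    expect_true(all(pop$age >= spec$age_range[1] &
                      pop$age <= spec$age_range[2]))
    expect_true(all(pop$weight > 0 & pop$gfr > 0 & pop$albumin > 0))
  }
})
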