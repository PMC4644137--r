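test_that("GMR is exact on scaled groups and guarded on bad input", {
  set.seed(301)
  x <- rlnorm(20)
  g <- gmr_ci(x, x)
  expect_equal(g$gmr, 1.0)
  expect_true(g$ci_low <= 1 && 1 <= g$ci_high)
  g2 <- gmr_ci(2 * x, x)
  expect_equal(g2$gmr, 2.0, tolerance = 1e-12)
  expect_error(gmr_ci(c(1, -1, 2), x), "positive")
  expect_error(gmr_ci(1, x), "n >= 2")
})

test_that("fold change is the ratio of arithmetic means", {
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fold_change(c(2, 4, 6), c(1, 2, 3)), 2)
  set.seed(302)
  x <- rlnorm(10); y <- rlnorm(10)
  expect_equal(fold_change(3.7 * x, y), 3.7 * fold_change(x, y))
  expect_error(fold_change(x, -y), "positive")
})

test_that("GMR and fold change agree to first order for equal CVs", {
  set.seed(303)
  ctrl <- rlnorm(500, meanlog = 1, sdlog = 0.2)
  test <- rlnorm(500, meanlog = 1.3, sdlog = 0.2)
  expect_equal(gmr_ci(test, ctrl)$gmr, fold_change(test, ctrl),
               tolerance = 0.03)
})

test_that("Dunnett reduces to the pooled t-test with one comparison", {
  set.seed(304)
  a <- rlnorm(30); b <- rlnorm(30, meanlog = 0.3)
  p_d <- dunnett_anova(list(ctrl = a, trt = b), "ctrl")
  p_t <- t.test(log(b), log(a), var.equal = TRUE)$p.value
  expect_equal(unname(p_d["trt"]), p_t, tolerance = 1e-6)
})

test_that("Dunnett adjustment never decreases the unadjusted p", {
  set.seed(305)
  groups <- c(list(ctrl = rlnorm(25)),
              lapply(1:4, function(i) rlnorm(25, meanlog = 0.1 * i)))
  names(groups)[-1] <- paste0("g", 1:4)
  p_adj <- dunnett_anova(groups, "ctrl")
  for (g in names(groups)[-1]) {
    p_raw <- t.test(log(groups[[g]]), log(groups$ctrl),
                    var.equal = TRUE)$p.value
    expect_gte(p_adj[g] + 1e-8, p_raw)
  }
})

test_that("a control copy is not flagged as different", {
  set.seed(306)
  a <- rlnorm(40)
  p <- dunnett_anova(list(ctrl = a, copy = a, other = rlnorm(40)), "ctrl")
  expect_gt(p["copy"], 0.95)
})

test_that("Dunnett family-wise type-I error is near nominal under the null", {
  set.seed(307)
  n_rej <- 0L
  n_rep <- 600L
  for (r in seq_len(n_rep)) {
    g <- list(ctrl = rlnorm(25), a = rlnorm(25), b = rlnorm(25))
    n_rej <- n_rej + any(dunnett_anova(g, "ctrl") < 0.05)
  }
  rate <- n_rej / n_rep
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("cohort comparison table is internally consistent", {
  d <- trial_design(n_trials = 3, n_subjects = 8, global_seed = 5)
  studies <- list(healthy = run_study(d, "healthy", fit_biexp = FALSE),
                  renal_sev = run_study(d, "renal_sev", fit_biexp = FALSE))
  cmp <- compare_cohorts(studies, parameters = c("auc_inf", "cl_obs"))
  ctrl_rows <- cmp[cmp$cohort == "healthy", ]
  expect_true(all(ctrl_rows$gmr == 1))
  test_rows <- cmp[cmp$cohort == "renal_sev", ]
  expect_true(all(test_rows$ci_low <= test_rows$gmr &
                    test_rows$gmr <= test_rows$ci_high))
  # equivalence flag is exactly the 0.8-1.2 window
  expect_equal(test_rows$equivalent,
               test_rows$gmr >= 0.8 & test_rows$gmr <= 1.2)
  auc_row <- cmp[cmp$parameter == "auc_inf" & cmp$cohort == "renal_sev", ]
  expect_gt(auc_row$gmr, 1.2)   # severe renal impairment raises exposure
  expect_lt(auc_row$p_adjusted, 0.001)
  expect_equal(auc_row$stars, "***")
})
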