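# Independent numerical oracle: integrate the two-compartment bolus system
# (central amount A1 with elimination k10, peripheral A2, urine U) with a
# Runge-Kutta solver and return concentrations on the requested grid.
ode_oracle <- function(subject, dose, times) {
  k10 <- subject$cl_renal / subject$v1
  k12 <- subject$q_inter / subject$v1
  k21 <- subject$q_inter / subject$v2
  rhs <- function(t, y, p) {
    list(c(-(k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2],
           k10 * y[1]))
  }
  out <- deSolve::ode(y = c(A1 = dose, A2 = 0, U = 0), times = times,
                      func = rhs, parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-10)
  list(times = out[, "time"], conc = out[, "A1"] / subject$v1,
       urine = out[, "U"])
}

# random but physiologic subject parameter sets for property tests
random_subject <- function() {
  v1 <- runif(1, 2, 8)
  v2 <- runif(1, 3, 15)
  q <- runif(1, 1, 8)
  cl <- runif(1, 0.1, 1.5)
  subject_pk(v1, v2, q, cl)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
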