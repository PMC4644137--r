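#' Linear-trapezoid area under the curve
#'
#' Integrates a concentration-time profile on its grid up to `upto`,
#' interpolating linearly if `upto` falls between grid points.
#'
#' @param times Strictly increasing time grid, h.
#' @param conc Concentrations on the grid, mg/L.
#' @param upto Upper integration limit, h; must lie within the grid range.
#' @return AUC in mg*h/L.
#' @examples
#' auc_trapezoid(0:10, rep(1, 11), 10)  # 10
#' @export
auc_trapezoid <- function(times, conc, upto = max(times)) {
  if (length(times) != length(conc) || any(diff(times) <= 0))
    stop("times must be strictly increasing and match conc in length",
         call. = FALSE)
  if (upto < times[1] || upto > times[length(times)])
    stop(sprintf("upto = %g h is outside the grid [%g, %g]",
                 upto, times[1], times[length(times)]), call. = FALSE)
  if (upto == times[1]) return(0)
  keep <- times <= upto
  tt <- times[keep]; cc <- conc[keep]
  if (upto > tt[length(tt)]) {
    c_up <- stats::approx(times, conc, xout = upto)$y
    tt <- c(tt, upto); cc <- c(cc, c_up)
  }
  sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
}

#' Terminal log-linear slope and half-life
#'
#' Least-squares fit of `ln C` against time over a window (default: the
#' final 24 h of the profile); `lambda_z` is minus the slope and the
#' half-life is `ln 2 / lambda_z`.
#'
#' @param times,conc Profile grid and concentrations.
#' @param window Two-element time range to fit over, h.
#' @return List with `lambda_z` (1/h), `t_half` (h), `intercept` (ln mg/L),
#'   `n` points used.
#' @examples
#' t <- 0:72
#' lambda_z_fit(t, exp(-0.05 * t))$t_half  # ln(2)/0.05
#' @export
lambda_z_fit <- function(times, conc, window = max(times) - c(24, 0)) {
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 3L)
    stop("lambda_z fit needs at least 3 points in the window", call. = FALSE)
  if (any(conc[keep] <= 0))
    stop("non-positive concentrations in the lambda_z window", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, times[keep]), log(conc[keep]))
  lz <- -fit$coefficients[2]
  if (!is.finite(lz) || lz <= 0)
    stop("terminal slope is not negative; lambda_z undefined", call. = FALSE)
  list(lambda_z = unname(lz), t_half = log(2) / unname(lz),
       intercept = unname(fit$coefficients[1]), n = sum(keep))
}

#' Bi-exponential fit of a bolus profile
#'
#' Nonlinear least squares of `A e^{-alpha t} + B e^{-beta t}` initialized by
#' curve stripping (terminal log-linear fit, residual early-phase fit), with
#' `alpha > beta` enforced by ordering. Degenerate (effectively
#' mono-exponential) profiles are rejected.
#'
#' @param times,conc Profile grid and concentrations (>= 6 points spanning
#'   both phases).
#' @param terminal_window Window for the stripping terminal fit, h.
#' @return List with `t_half_dist` and `t_half_elim` (h), rates `alpha`,
#'   `beta` (1/h), amplitudes `A`, `B` (mg/L), and `fit` (the nls object).
#' @examples
#' t <- default_time_grid()
#' y <- 370 * exp(-1.44 * t) + 180 * exp(-0.043 * t)
#' biexp_fit(t, y)[c("t_half_dist", "t_half_elim")]
#' @export
biexp_fit <- function(times, conc, terminal_window = max(times) - c(24, 0)) {
  if (length(times) < 6L)
    stop("bi-exponential fit needs at least 6 points", call. = FALSE)
  if (any(conc <= 0))
    stop("bi-exponential fit needs positive concentrations", call. = FALSE)
  term <- lambda_z_fit(times, conc, terminal_window)
  b0 <- term$lambda_z
  B0 <- exp(term$intercept)
  resid_early <- conc - B0 * exp(-b0 * times)
  early <- resid_early > 0.01 * conc & times < terminal_window[1]
  if (sum(early) < 3L)
    stop("degenerate profile: no resolvable distribution phase ",
         "(mono-exponential input?)", call. = FALSE)
  strip <- stats::lm.fit(cbind(1, times[early]), log(resid_early[early]))
  a0 <- max(-unname(strip$coefficients[2]), 2 * b0)
  A0 <- exp(unname(strip$coefficients[1]))
  df <- data.frame(t = times, y = conc)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-a * t) + B * exp(-b * t), data = df,
    start = list(A = A0, a = a0, B = B0, b = b0),
    lower = c(0, 1e-6, 0, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  if (p["a"] < p["b"]) p <- c(A = unname(p["B"]), a = unname(p["b"]),
                              B = unname(p["A"]), b = unname(p["a"]))
  if (p["a"] / p["b"] < 3 || p["A"] < 1e-6 * p["B"])
    stop("degenerate bi-exponential fit: phases not separable ",
         sprintf("(alpha/beta = %.2f)", p["a"] / p["b"]), call. = FALSE)
  list(t_half_dist = log(2) / unname(p["a"]),
       t_half_elim = log(2) / unname(p["b"]),
       alpha = unname(p["a"]), beta = unname(p["b"]),
       A = unname(p["A"]), B = unname(p["B"]), fit = fit)
}

#' Non-compartmental analysis of one profile
#'
#' Model-blind summary of a concentration-time/urine profile: Cmax and tmax
#' from the observed maximum, AUC(0-last) by linear trapezoid, terminal
#' `lambda_z` over the final 24 h, `AUC(0-Inf) = AUC(0-last) +
#' C_last/lambda_z`, observed clearance `dose/AUC(0-Inf)` (also per kg),
#' fraction excreted in urine by 72 h, the 1-h concentration by
#' interpolation, and (optionally) both half-lives from a bi-exponential
#' fit.
#'
#' @param profile A `"pk_profile"` object (or any list with `times`,
#'   `conc_plasma`, `urine_cum`, `dose`).
#' @param weight Subject body weight, kg (for CL per kg).
#' @param fit_biexp Fit the bi-exponential model for the observed
#'   distribution half-life? (Slightly slower; `lambda_z` is always fitted.)
#' @return Object of class `"nca_summary"`: named list with `cmax`, `tmax`,
#'   `auc_last`, `auc_inf`, `lambda_z`, `t_half_elim_obs`,
#'   `t_half_dist_obs`, `cl_obs` (L/h), `cl_per_kg` (mL/h/kg), `fe_72`,
#'   `c_at_1h`, `dose`, `weight`.
#' @examples
#' prof <- simulate_iv_bolus(reference_subject(), 2220)
#' nca_summary(prof, weight = 74)
#' @export
nca_summary <- function(profile, weight, fit_biexp = TRUE) {
  t <- profile$times; y <- profile$conc_plasma
  imax <- which.max(y)
  auc_last <- auc_trapezoid(t, y)
  lz <- lambda_z_fit(t, y)
  auc_inf <- auc_last + y[length(y)] / lz$lambda_z
  cl_obs <- profile$dose / auc_inf
  fe72 <- if (!is.null(profile$urine_cum) && max(t) >= 72)
    fraction_excreted(profile, 72) else NA_real_
  c1h <- if (max(t) >= 1) stats::approx(t, y, xout = 1)$y else NA_real_
  thd <- if (fit_biexp) tryCatch(biexp_fit(t, y)$t_half_dist,
                                 error = function(e) NA_real_) else NA_real_
  structure(list(cmax = y[imax], tmax = t[imax],
                 auc_last = auc_last, auc_inf = auc_inf,
                 lambda_z = lz$lambda_z, t_half_elim_obs = lz$t_half,
                 t_half_dist_obs = thd,
                 cl_obs = cl_obs, cl_per_kg = cl_obs / weight * 1000,
                 fe_72 = fe72, c_at_1h = c1h,
                 dose = profile$dose, weight = weight),
            class = "nca_summary")
}

#' @export
print.nca_summary <- function(x, ...) {
  cat("Non-compartmental summary\n")
  cat(sprintf("  Cmax %.1f mg/L at t = %g h; C(1 h) %.1f mg/L\n",
              x$cmax, x$tmax, x$c_at_1h))
  cat(sprintf("  AUC(0-last) %.0f, AUC(0-Inf) %.0f mg*h/L\n",
              x$auc_last, x$auc_inf))
  cat(sprintf("  CL %.3f L/h (%.2f mL/h/kg); t1/2 elim %.2f h%s\n",
              x$cl_obs, x$cl_per_kg, x$t_half_elim_obs,
              if (is.finite(x$t_half_dist_obs))
                sprintf(", t1/2 dist %.3f h", x$t_half_dist_obs) else ""))
  if (is.finite(x$fe_72))
    cat(sprintf("  fe(72 h) %.3f\n", x$fe_72))
  invisible(x)
}
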