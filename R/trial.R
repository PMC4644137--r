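#' In-silico clinical trial design
#'
#' Defaults reproduce the published study design: 10 trials of 10 subjects
#' (half female, assigned deterministically), 30 mg/kg IV bolus, 72-h
#' horizon.
#'
#' @param n_trials Number of trials.
#' @param n_subjects Subjects per trial.
#' @param prop_female Fraction of females per trial; the first
#'   `ceiling(prop_female * n_subjects)` slots are female so the fraction is
#'   exact at the default design.
#' @param dose_per_kg IV dose, mg/kg.
#' @param horizon Simulation horizon, h.
#' @param global_seed Integer seed; all randomness derives from it through a
#'   counter-based (seed, cohort, trial, subject) scheme, so results are
#'   reproducible independent of execution order.
#' @return Object of class `"trial_design"`.
#' @export
trial_design <- function(n_trials = 10, n_subjects = 10, prop_female = 0.5,
                         dose_per_kg = 30, horizon = 72,
                         global_seed = 20140612) {
  if (n_trials < 1 || n_subjects < 1)
    stop("counts must be positive", call. = FALSE)
  if (prop_female < 0 || prop_female > 1)
    stop("prop_female must be in [0, 1]", call. = FALSE)
  if (dose_per_kg <= 0 || horizon <= 0)
    stop("dose_per_kg and horizon must be positive", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials),
                 n_subjects = as.integer(n_subjects),
                 prop_female = prop_female, dose_per_kg = dose_per_kg,
                 horizon = horizon, global_seed = as.integer(global_seed)),
            class = "trial_design")
}

#' Run an in-silico clinical trial study for one cohort
#'
#' For every trial and subject: samples a virtual individual from the
#' cohort (females in the leading slots), maps physiology to subject PK,
#' doses `dose_per_kg * weight` mg as an IV bolus, simulates the analytic
#' profile over the horizon and summarises it by NCA. Identical inputs give
#' bit-identical output.
#'
#' @param design A [trial_design()].
#' @param cohort A [cohort_spec()] or a built-in cohort label.
#' @param compound A [compound_params()].
#' @param times Sampling grid; default [default_time_grid()] over the
#'   horizon.
#' @param fit_biexp Fit per-subject bi-exponential half-lives in NCA?
#' @return Object of class `"pk_study"`: `subjects` (one row per subject:
#'   physiology, dose and all NCA parameters), `times`, `conc` and `urine`
#'   (time-by-subject matrices), `envelope` (mean and 5th/95th percentile
#'   bands), plus the design/cohort/compound used.
#' @examples
#' st <- run_study(trial_design(n_trials = 2, n_subjects = 4), "healthy",
#'                 fit_biexp = FALSE)
#' summary(st)
#' @export
run_study <- function(design = trial_design(), cohort = "healthy",
                      compound = compound_params(),
                      times = default_time_grid(design$horizon),
                      fit_biexp = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  if (is.character(cohort)) cohort <- get_cohort(cohort)
  stopifnot(inherits(cohort, "cohort_spec"))
  n_f <- ceiling(design$prop_female * design$n_subjects)
  n_total <- design$n_trials * design$n_subjects
  conc <- matrix(NA_real_, length(times), n_total)
  urine <- matrix(NA_real_, length(times), n_total)
  rows <- vector("list", n_total)
  k <- 0L
  for (tr in seq_len(design$n_trials)) {
    for (su in seq_len(design$n_subjects)) {
      k <- k + 1L
      sex <- if (su <= n_f) "F" else "M"
      ind <- sample_individual(
        cohort, sex,
        seed = subject_seed(design$global_seed, cohort$label, tr, su),
        id = sprintf("%s_t%02d_s%02d", cohort$label, tr, su))
      pk <- subject_pk_from_physiology(ind, compound, cohort)
      dose <- design$dose_per_kg * ind$weight
      prof <- simulate_iv_bolus(pk, dose, times)
      nca <- nca_summary(prof, ind$weight, fit_biexp = fit_biexp)
      conc[, k] <- prof$conc_plasma
      urine[, k] <- prof$urine_cum
      rows[[k]] <- data.frame(
        id = ind$id, trial = tr, subject = su, sex = sex,
        age = ind$age, weight = ind$weight, gfr = ind$gfr,
        albumin = ind$albumin, fu = pk$fu,
        cl_true = pk$cl_renal, dose = dose,
        cmax = nca$cmax, tmax = nca$tmax,
        auc_last = nca$auc_last, auc_inf = nca$auc_inf,
        lambda_z = nca$lambda_z, t_half_elim_obs = nca$t_half_elim_obs,
        t_half_dist_obs = nca$t_half_dist_obs,
        cl_obs = nca$cl_obs, cl_per_kg = nca$cl_per_kg,
        fe_72 = nca$fe_72, c_at_1h = nca$c_at_1h)
    }
  }
  subjects <- do.call(rbind, rows)
  structure(list(cohort = cohort, design = design, compound = compound,
                 subjects = subjects, times = times,
                 conc = conc, urine = urine,
                 envelope = percentile_envelope(conc, times = times)),
            class = "pk_study")
}

#' Point-wise mean and percentile envelope of simulated profiles
#'
#' @param profiles Time-by-subject matrix of concentrations, or a list of
#'   `"pk_profile"` objects on a common grid.
#' @param q_low,q_high Quantile pair (default 5th/95th percentile).
#' @param times Optional grid to attach to the result.
#' @return Data frame with columns `time`, `mean`, `low`, `high`.
#' @export
percentile_envelope <- function(profiles, q_low = 0.05, q_high = 0.95,
                                times = NULL) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    grids <- lapply(profiles, `[[`, "times")
    if (length(profiles) < 2L)
      stop("need at least 2 profiles", call. = FALSE)
    for (g in grids[-1])
      if (!isTRUE(all.equal(g, grids[[1]])))
        stop("grid mismatch: profiles are not on a common time grid",
             call. = FALSE)
    times <- grids[[1]]
    profiles <- vapply(profiles, `[[`, numeric(length(times)), "conc_plasma")
  }
  if (ncol(profiles) < 2L)
    stop("need at least 2 profiles", call. = FALSE)
  if (q_low > q_high) stop("q_low must not exceed q_high", call. = FALSE)
  data.frame(
    time = if (is.null(times)) seq_len(nrow(profiles)) else times,
    mean = rowMeans(profiles),
    low = apply(profiles, 1, stats::quantile, probs = q_low, names = FALSE),
    high = apply(profiles, 1, stats::quantile, probs = q_high, names = FALSE))
}

study_parameters <- c("dose", "cmax", "auc_last", "auc_inf", "cl_obs",
                      "cl_per_kg", "fe_72", "c_at_1h", "t_half_elim_obs")

#' @export
print.pk_study <- function(x, ...) {
  d <- x$design
  cat(sprintf("In-silico study: cohort '%s', %d trials x %d subjects, %g mg/kg IV, %g h\n",
              x$cohort$label, d$n_trials, d$n_subjects, d$dose_per_kg,
              d$horizon))
  s <- x$subjects
  cat(sprintf("  pooled mean Cmax %.1f mg/L, AUCinf %.0f mg*h/L, CL %.3f L/h, fe(72) %.3f\n",
              mean(s$cmax), mean(s$auc_inf), mean(s$cl_obs), mean(s$fe_72)))
  invisible(x)
}

#' Summarise a study: pooled and per-trial means and SDs
#'
#' Pooled statistics are computed over all subjects (not over trial means);
#' per-trial means are also returned.
#'
#' @param object A `"pk_study"`.
#' @param ... Unused.
#' @return Object of class `"summary.pk_study"` with elements `pooled`
#'   (data frame: parameter, mean, sd, n) and `by_trial`.
#' @export
summary.pk_study <- function(object, ...) {
  s <- object$subjects
  pars <- intersect(study_parameters, names(s))
  pooled <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(s[[p]], na.rm = TRUE), 0),
    sd = vapply(pars, function(p) stats::sd(s[[p]], na.rm = TRUE), 0),
    n = nrow(s), row.names = NULL)
  by_trial <- do.call(rbind, lapply(split(s, s$trial), function(d) {
    cbind(data.frame(trial = d$trial[1]),
          as.data.frame(lapply(d[pars], mean, na.rm = TRUE)))
  }))
  rownames(by_trial) <- NULL
  structure(list(cohort = object$cohort$label, pooled = pooled,
                 by_trial = by_trial),
            class = "summary.pk_study")
}

#' @export
print.summary.pk_study <- function(x, ...) {
  cat(sprintf("Study summary, cohort '%s' (n = %d subjects)\n",
              x$cohort, x$pooled$n[1]))
  print(transform(x$pooled, mean = signif(mean, 5), sd = signif(sd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Semi-log plot of the mean profile with percentile bands
#'
#' @param x A `"pk_study"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pk_study <- function(x, ...) {
  e <- x$envelope
  graphics::plot(e$time, e$mean, type = "n", log = "y",
                 ylim = range(e$low[e$low > 0], e$high),
                 xlab = "Time (h)", ylab = "Plasma concentration (mg/L)",
                 main = sprintf("Cohort: %s", x$cohort$label), ...)
  graphics::polygon(c(e$time, rev(e$time)), c(e$low, rev(e$high)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(e$time, e$mean, lwd = 2, col = "steelblue4")
  invisible(x)
}
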