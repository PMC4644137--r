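#' Run the full multi-cohort replication study
#'
#' Executes the default in-silico study end-to-end: all eight cohorts at
#' 10 trials x 10 subjects (unless the config overrides the design), NCA
#' per subject, cohort summary table (mean +/- SD of dose, Cmax, AUC, CL,
#' fe), a healthy-cohort validation table (Cmax, C at 1 h, fu, CL/kg,
#' fe(72), renal AUC fold-increases), the between-cohort comparison, and
#' figures (semi-log profile envelopes, GMR forest, GFR-clearance scatter,
#' cumulative urinary recovery). All artifacts are written as CSV/JSON (and
#' plots) under `out_dir`, with a manifest recording the seed and the
#' config hash.
#'
#' @param config Config list (default [default_config()]).
#' @param out_dir Output directory; created if missing. `NULL` skips all
#'   file output and returns results only.
#' @param cohorts Optional character vector restricting the cohorts run.
#' @param fit_biexp Fit per-subject bi-exponential half-lives?
#' @param quiet Suppress the one-line-per-cohort progress log?
#' @return Invisibly, a list with `studies` (named list of `"pk_study"`),
#'   `summary_table`, `validation`, `comparison`, `config`, and `paths` of
#'   written files.
#' @export
run_full_study <- function(config = default_config(), out_dir = NULL,
                            cohorts = NULL, fit_biexp = TRUE,
                            quiet = FALSE) {
  validate_config(config)
  compound <- compound_from_config(config)
  design <- design_from_config(config)
  specs <- cohorts_from_config(config)
  if (!is.null(cohorts)) specs <- specs[cohorts]
  studies <- list()
  for (lab in names(specs)) {
    if (!quiet)
      message(sprintf("cohort %-12s seed %d: %d trials x %d subjects",
                      lab, design$global_seed, design$n_trials,
                      design$n_subjects))
    studies[[lab]] <- run_study(design, specs[[lab]], compound,
                                fit_biexp = fit_biexp)
  }
  summary_table <- study_summary_table(studies)
  comparison <- if (length(studies) > 1 && "healthy" %in% names(studies))
    compare_cohorts(studies, control = "healthy") else NULL
  validation <- if ("healthy" %in% names(studies))
    validation_table(studies, compound) else NULL
  paths <- character(0)
  if (!is.null(out_dir)) {
    paths <- write_study_outputs(studies, summary_table, validation,
                                 comparison, config, out_dir)
  }
  invisible(list(studies = studies, summary_table = summary_table,
                 validation = validation, comparison = comparison,
                 config = config, paths = paths))
}

# cohort-level mean (SD) table of the headline PK parameters
study_summary_table <- function(studies) {
  do.call(rbind, lapply(names(studies), function(lab) {
    s <- studies[[lab]]$subjects
    data.frame(
      cohort = lab, n = nrow(s),
      dose_mean = mean(s$dose), dose_sd = stats::sd(s$dose),
      cmax_mean = mean(s$cmax), cmax_sd = stats::sd(s$cmax),
      auc_mean = mean(s$auc_inf), auc_sd = stats::sd(s$auc_inf),
      cl_mean = mean(s$cl_obs), cl_sd = stats::sd(s$cl_obs),
      fe_mean = mean(s$fe_72), fe_sd = stats::sd(s$fe_72))
  }))
}

# healthy-cohort validation quantities plus renal AUC fold-increases
validation_table <- function(studies, compound) {
  h <- studies$healthy$subjects
  fu <- fraction_unbound(compound$kd_albumin, albumin_g_per_l_to_um(45))
  out <- data.frame(
    quantity = c("cmax_mg_l", "c_at_1h_mg_l", "fu", "cl_ml_h_kg", "fe_72"),
    value = c(mean(h$cmax), mean(h$c_at_1h), fu, mean(h$cl_per_kg),
              mean(h$fe_72)))
  for (lab in c("renal_mod", "renal_sev")) {
    if (lab %in% names(studies))
      out <- rbind(out, data.frame(
        quantity = paste0("auc_fold_", lab),
        value = fold_change(studies[[lab]]$subjects$auc_inf, h$auc_inf)))
  }
  out
}

write_study_outputs <- function(studies, summary_table, validation,
                                comparison, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  for (lab in names(studies)) {
    if (isTRUE(config$output$write_profiles))
      paths <- c(paths, write_profiles_csv(
        studies[[lab]], file.path(out_dir, sprintf("profiles_%s.csv", lab))))
    paths <- c(paths, save_csv(studies[[lab]]$subjects,
                               sprintf("nca_%s.csv", lab)))
  }
  paths <- c(paths, save_csv(summary_table, "summary_table.csv"))
  if (!is.null(validation))
    paths <- c(paths, save_csv(validation, "validation.csv"))
  if (!is.null(comparison))
    paths <- c(paths, save_csv(as.data.frame(comparison), "comparison.csv"))
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(summary = summary_table,
                            validation = validation),
                       sj, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, sj)
  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_config(config, cfg_path)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(global_seed = config$design$global_seed,
         config_file = basename(cfg_path),
         config_md5 = unname(tools::md5sum(cfg_path)),
         cohorts = names(studies),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    manifest, auto_unbox = TRUE)
  paths <- c(paths, cfg_path, manifest)
  if (isTRUE(config$output$write_plots))
    paths <- c(paths, write_study_plots(studies, comparison, config, out_dir))
  paths
}

write_study_plots <- function(studies, comparison, config, out_dir) {
  fmt <- config$output$plot_format %||% "png"
  dev_open <- function(name, width = 7, height = 5) {
    p <- file.path(out_dir, paste0(name, ".", fmt))
    if (fmt == "svg") grDevices::svg(p, width = width, height = height)
    else grDevices::png(p, width = width * 100, height = height * 100)
    p
  }
  paths <- character(0)
  for (lab in names(studies)) {
    paths <- c(paths, dev_open(paste0("profile_", lab)))
    plot(studies[[lab]])
    grDevices::dev.off()
  }
  if (!is.null(comparison)) {
    paths <- c(paths, dev_open("gmr_forest", width = 10))
    plot(comparison, parameters = c("cmax", "auc_inf", "cl_obs"))
    grDevices::dev.off()
  }
  all_subj <- do.call(rbind, lapply(studies, `[[`, "subjects"))
  paths <- c(paths, dev_open("gfr_vs_cl"))
  graphics::plot(all_subj$gfr, all_subj$cl_obs, pch = 19, cex = 0.5,
                 xlab = "GFR (mL/min)", ylab = "Systemic CL (L/h)",
                 main = "GFR vs systemic clearance, all cohorts")
  graphics::abline(stats::lm(cl_obs ~ gfr, data = all_subj), col = "red3")
  grDevices::dev.off()
  paths <- c(paths, dev_open("urine_recovery"))
  first <- TRUE
  cols <- grDevices::hcl.colors(length(studies), "Dark 3")
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    mean_urine <- rowMeans(st$urine)
    if (first) {
      graphics::plot(st$times, mean_urine, type = "l", col = cols[i],
                     xlab = "Time (h)", ylab = "Cumulative urine (mg)",
                     main = "Mean urinary recovery", lwd = 2,
                     ylim = c(0, 1.05 * max(vapply(studies, function(s)
                       max(rowMeans(s$urine)), 0))))
      first <- FALSE
    } else graphics::lines(st$times, mean_urine, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(studies), col = cols,
                   lwd = 2, cex = 0.7)
  grDevices::dev.off()
  paths
}
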