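#' Default study configuration
#'
#' The embedded configuration that reproduces the published in-silico
#' study: default compound parameters, the eight built-in cohorts, and the
#' 10 x 10 trial design. [read_config()] merges a user file over these
#' defaults.
#'
#' @return Nested list with sections `compound`, `cohorts`, `design`,
#'   `output`.
#' @export
default_config <- function() {
  cmp <- compound_params()
  list(
    compound = list(
      molecular_weight = cmp$molecular_weight,
      dose_per_kg = cmp$dose_per_kg,
      cl_ref = cmp$cl_ref,
      vss_per_kg = cmp$vss_per_kg,
      v1_per_kg = cmp$v1_per_kg,
      t_half_dist = cmp$t_half_dist,
      t_half_elim = cmp$t_half_elim,
      kd_albumin = cmp$kd_albumin,
      fu_override = NULL,
      pka_acid = cmp$pka_acid, pka_base = cmp$pka_base,
      logp = cmp$logp, psa = cmp$psa),
    cohorts = list(),
    design = list(n_trials = 10, n_subjects = 10, prop_female = 0.5,
                  dose_per_kg = 30, horizon = 72, global_seed = 20140612),
    output = list(write_profiles = TRUE, write_plots = TRUE,
                  plot_format = "png"))
}

config_known_keys <- function() {
  list(compound = names(default_config()$compound),
       design = names(default_config()$design),
       output = names(default_config()$output),
       cohorts = setdiff(names(formals(cohort_spec)), "label"))
}

validate_config <- function(cfg) {
  known <- config_known_keys()
  bad_top <- setdiff(names(cfg), c("compound", "cohorts", "design", "output"))
  if (length(bad_top))
    stop("unknown config section(s): ", paste(bad_top, collapse = ", "),
         call. = FALSE)
  for (sec in intersect(names(cfg), c("compound", "design", "output"))) {
    bad <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(bad))
      stop(sprintf("unknown config key(s) under '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (lab in names(cfg$cohorts)) {
    bad <- setdiff(names(cfg$cohorts[[lab]]), known$cohorts)
    if (length(bad))
      stop(sprintf("unknown config key(s) under 'cohorts.%s': %s", lab,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(cfg)
}

#' Read a study configuration file
#'
#' YAML with sections `compound`, `cohorts`, `design`, `output`. Unknown
#' keys are rejected with their path; missing keys fall back to the
#' embedded defaults of [default_config()], which reproduce the published
#' study.
#'
#' @param path Path to a YAML file.
#' @return Validated, merged config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
  cfg <- default_config()
  for (sec in c("compound", "design", "output"))
    for (key in names(user[[sec]]))
      cfg[[sec]][[key]] <- user[[sec]][[key]]
  cfg$cohorts <- user$cohorts %||% list()
  validate_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study configuration file
#'
#' @param config Config list (as from [default_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a compound from a config
#'
#' @param config Config list.
#' @return A [compound_params()].
#' @export
compound_from_config <- function(config) {
  do.call(compound_params, config$compound)
}

#' Build the trial design from a config
#'
#' @param config Config list.
#' @return A [trial_design()].
#' @export
design_from_config <- function(config) {
  do.call(trial_design, config$design)
}

#' Build the cohort map from a config
#'
#' Starts from [builtin_cohorts()] and applies any per-cohort overrides in
#' the config's `cohorts` section; an unknown label defines a new cohort and
#' must provide at least `weight_mean` and `gfr_mean`.
#'
#' @param config Config list.
#' @return Named list of [cohort_spec()] objects.
#' @export
cohorts_from_config <- function(config) {
  specs <- builtin_cohorts()
  for (lab in names(config$cohorts)) {
    over <- config$cohorts[[lab]]
    if (lab %in% names(specs)) {
      base <- unclass(specs[[lab]])
      if (any(c("gfr_mean", "gfr_sd") %in% names(over)) &&
          !"gfr_bounds" %in% names(over))
        base$gfr_bounds <- NULL  # recompute from the overridden mean/sd
      args <- utils::modifyList(base, over)
    } else {
      if (!all(c("weight_mean", "gfr_mean") %in% names(over)))
        stop(sprintf("new cohort '%s' needs weight_mean and gfr_mean", lab),
             call. = FALSE)
      args <- c(list(label = lab), over)
    }
    args$label <- lab
    if (!is.null(over$gfr_bounds)) args$gfr_bounds <- unlist(over$gfr_bounds)
    if (!is.null(args$age_range)) args$age_range <- unlist(args$age_range)
    specs[[lab]] <- do.call(cohort_spec, args)
  }
  specs
}
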