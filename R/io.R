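profile_csv_columns <- c("subject_id", "trial", "time_h", "conc_mg_per_l",
                         "urine_cum_mg")

#' Write study profiles to tidy CSV
#'
#' One row per (subject, time point), columns `subject_id`, `trial`,
#' `time_h`, `conc_mg_per_l`, `urine_cum_mg`. Numbers are written with 12
#' significant digits so a write-read round trip is exact at that
#' precision.
#'
#' @param study A `"pk_study"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(study, path) {
  stopifnot(inherits(study, "pk_study"))
  n_t <- length(study$times)
  n_s <- nrow(study$subjects)
  df <- data.frame(
    subject_id = rep(study$subjects$id, each = n_t),
    trial = rep(study$subjects$trial, each = n_t),
    time_h = sprintf("%.12g", rep(study$times, n_s)),
    conc_mg_per_l = sprintf("%.12g", as.vector(study$conc)),
    urine_cum_mg = sprintf("%.12g", as.vector(study$urine)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profiles CSV back into per-subject profiles
#'
#' Accepts the dialect written by [write_profiles_csv()] (header row,
#' comma-separated, UTF-8, '.' decimal). Malformed input produces a parse
#' error naming the problem.
#'
#' @param path CSV path.
#' @return Named list (by subject id) of lists with `times`, `conc_plasma`,
#'   `urine_cum`, `trial`, `subject_ref`.
#' @export
read_profiles_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("profiles file '%s' does not exist", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("parse error: empty profiles file", call. = FALSE)
  header <- strsplit(first, ",", fixed = TRUE)[[1]]
  missing <- setdiff(profile_csv_columns, header)
  if (length(missing))
    stop("parse error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time_h", "conc_mg_per_l", "urine_cum_mg")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                   !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value in column '%s', line %d",
                   col, bad[1] + 1L), call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  if (nrow(df) == 0L)
    stop("parse error: profiles file has a header but no rows", call. = FALSE)
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$time_h), ]
    list(times = d$time_h, conc_plasma = d$conc_mg_per_l,
         urine_cum = d$urine_cum_mg, trial = d$trial[1],
         subject_ref = d$subject_id[1])
  })
  out[unique(df$subject_id)]
}

#' Run stand-alone NCA on a profiles CSV
#'
#' Reads profiles in the [write_profiles_csv()] dialect, attaches dose and
#' weight from a subject table, and returns one NCA row per subject.
#'
#' @param path Profiles CSV.
#' @param weights Data frame with columns `subject_id`, `weight`, `dose`.
#' @param fit_biexp Fit per-subject bi-exponential half-lives?
#' @return Data frame of NCA summaries, one row per subject.
#' @export
nca_from_csv <- function(path, weights, fit_biexp = FALSE) {
  need <- c("subject_id", "weight", "dose")
  if (!all(need %in% names(weights)))
    stop("weights needs columns subject_id, weight, dose", call. = FALSE)
  profs <- read_profiles_csv(path)
  rows <- lapply(names(profs), function(id) {
    w <- weights[weights$subject_id == id, ]
    if (nrow(w) != 1L)
      stop(sprintf("no unique weight/dose row for subject '%s'", id),
           call. = FALSE)
    p <- profs[[id]]
    p$dose <- w$dose
    s <- nca_summary(p, w$weight, fit_biexp = fit_biexp)
    cbind(data.frame(subject_id = id),
          as.data.frame(unclass(s)[setdiff(names(unclass(s)), "weight")]))
  })
  do.call(rbind, rows)
}
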