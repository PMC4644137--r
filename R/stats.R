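#' Geometric-mean ratio with confidence interval
#'
#' `GMR = exp(mean(ln test) - mean(ln control))`, with the confidence
#' interval from the pooled-variance two-sample t interval on the log scale,
#' back-transformed.
#'
#' @param test_values,control_values Positive samples (n >= 2 each).
#' @param level Confidence level (default 0.95).
#' @return List with `gmr`, `ci_low`, `ci_high`.
#' @examples
#' gmr_ci(c(2, 4, 8), c(1, 2, 4))$gmr  # exactly 2
#' @export
gmr_ci <- function(test_values, control_values, level = 0.95) {
  if (any(test_values <= 0) || any(control_values <= 0))
    stop("gmr requires strictly positive values", call. = FALSE)
  if (length(test_values) < 2L || length(control_values) < 2L)
    stop("gmr_ci needs n >= 2 per group", call. = FALSE)
  lt <- log(test_values); lc <- log(control_values)
  d <- mean(lt) - mean(lc)
  n1 <- length(lt); n2 <- length(lc)
  sp2 <- ((n1 - 1) * stats::var(lt) + (n2 - 1) * stats::var(lc)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n1 + n2 - 2)
  list(gmr = exp(d), ci_low = exp(d - tcrit * se),
       ci_high = exp(d + tcrit * se))
}

#' Arithmetic fold-change between group means
#'
#' @param test_values,control_values Numeric samples; the control mean must
#'   be positive.
#' @return `mean(test) / mean(control)`.
#' @export
fold_change <- function(test_values, control_values) {
  mc <- mean(control_values)
  if (!is.finite(mc) || mc <= 0)
    stop("control mean must be positive", call. = FALSE)
  mean(test_values) / mc
}

#' Many-to-one Dunnett comparisons on log-transformed values
#'
#' One-way ANOVA of `ln(value)` across groups followed by Dunnett's
#' many-to-one contrasts against the control, with adjusted p-values from
#' the multivariate-t reference distribution (via \pkg{multcomp}).
#'
#' @param groups Named list of positive numeric vectors (n >= 2 each).
#' @param control Name of the control group (must be in `groups`).
#' @return Named numeric vector of adjusted p-values, one per non-control
#'   group, names `"<group>"`.
#' @examples
#' set.seed(1)
#' g <- list(ctrl = rlnorm(20), a = rlnorm(20), b = rlnorm(20, 0.8))
#' dunnett_anova(g, "ctrl")
#' @export
dunnett_anova <- function(groups, control) {
  if (!control %in% names(groups))
    stop(sprintf("control group '%s' not found", control), call. = FALSE)
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  if (length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(unlist(groups) <= 0))
    stop("values must be positive (log-transformed internally)",
         call. = FALSE)
  lev <- c(control, setdiff(names(groups), control))
  df <- data.frame(
    y = log(unlist(groups, use.names = FALSE)),
    g = factor(rep(names(groups), ns), levels = lev))
  fit <- stats::aov(y ~ g, data = df)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ps <- summary(gl)$test$pvalues
  out <- as.numeric(ps)
  names(out) <- lev[-1]
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Compare cohorts of a multi-cohort study against a control
#'
#' For each PK parameter, computes per-cohort geometric means, geometric
#' mean ratios vs the control with pooled-t confidence intervals, Dunnett
#' adjusted p-values on the log scale, significance stars, an equivalence
#' flag against fixed bounds (default 0.8-1.2), and the arithmetic-mean
#' fold-change.
#'
#' @param studies Named list of `"pk_study"` objects (names are cohort
#'   labels), or a single list as returned by [run_full_study()]'s
#'   `studies` element.
#' @param control Label of the control cohort (default `"healthy"`).
#' @param parameters Parameters to compare.
#' @param level Confidence level for the GMR interval.
#' @param equivalence Two-element equivalence bounds on the GMR.
#' @param by_trial Use per-trial means instead of subject-level values as
#'   the analysis unit.
#' @return Object of class `"pk_comparison"`: a data frame with one row per
#'   (parameter, cohort).
#' @export
compare_cohorts <- function(studies, control = "healthy",
                            parameters = c("cmax", "auc_inf", "cl_obs",
                                           "fe_72"),
                            level = 0.95, equivalence = c(0.8, 1.2),
                            by_trial = FALSE) {
  if (is.null(names(studies)))
    names(studies) <- vapply(studies, function(s) s$cohort$label, "")
  if (!control %in% names(studies))
    stop(sprintf("control cohort '%s' not among studies", control),
         call. = FALSE)
  get_values <- function(study, par) {
    v <- study$subjects[[par]]
    if (by_trial)
      v <- vapply(split(v, study$subjects$trial), mean, 0)
    v[is.finite(v)]
  }
  rows <- list()
  for (par in parameters) {
    vals <- lapply(studies, get_values, par = par)
    pvals <- dunnett_anova(vals, control)
    for (lab in names(studies)) {
      g <- if (lab == control)
        list(gmr = 1, ci_low = NA_real_, ci_high = NA_real_)
      else gmr_ci(vals[[lab]], vals[[control]], level)
      p <- if (lab == control) NA_real_ else unname(pvals[lab])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, cohort = lab, control = control,
        n = length(vals[[lab]]),
        geo_mean = exp(mean(log(vals[[lab]]))),
        gmr = g$gmr, ci_low = g$ci_low, ci_high = g$ci_high,
        p_adjusted = p,
        stars = if (is.na(p)) "" else significance_stars(p),
        equivalent = g$gmr >= equivalence[1] & g$gmr <= equivalence[2],
        fold_change = fold_change(vals[[lab]], vals[[control]]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "equivalence") <- equivalence
  class(out) <- c("pk_comparison", "data.frame")
  out
}

#' @export
print.pk_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort comparison vs control '%s' (equivalence bounds %g-%g)\n",
              x$control[1], attr(x, "equivalence")[1],
              attr(x, "equivalence")[2]))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Forest plot of geometric-mean ratios
#'
#' One panel per parameter: GMR and its confidence interval per cohort, with
#' dashed reference lines at the equivalence bounds and a solid line at 1.
#'
#' @param x A `"pk_comparison"`.
#' @param parameters Which parameters to draw (default: all present).
#' @param ... Unused.
#' @export
plot.pk_comparison <- function(x, parameters = unique(x$parameter), ...) {
  eq <- attr(x, "equivalence")
  old <- graphics::par(mfrow = c(1, length(parameters)),
                       mar = c(4, 7, 2, 1))
  on.exit(graphics::par(old))
  for (par in parameters) {
    d <- x[x$parameter == par & x$cohort != x$control, ]
    yy <- rev(seq_len(nrow(d)))
    graphics::plot(d$gmr, yy, xlim = range(c(d$ci_low, d$ci_high, eq, 1),
                                           na.rm = TRUE),
                   ylim = c(0.5, nrow(d) + 0.5), yaxt = "n", pch = 19,
                   xlab = "GMR vs control", ylab = "", main = par)
    graphics::segments(d$ci_low, yy, d$ci_high, yy)
    graphics::abline(v = 1, col = "grey40")
    graphics::abline(v = eq, lty = 2, col = "grey40")
    graphics::axis(2, at = yy, labels = d$cohort, las = 1, cex.axis = 0.8)
  }
  invisible(x)
}
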