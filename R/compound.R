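#' Compound parameters for the contrast agent
#'
#' Bundles the physicochemical and pharmacokinetic inputs of the gadolinium
#' blood-pool agent. Defaults reproduce the published reference values for
#' gadofosveset: 30 mg/kg IV dose, steady-state volume 0.148 L/kg,
#' distribution half-life 0.48 h, elimination half-life 16.3 h, albumin
#' dissociation constant 85 uM, and a typical renal clearance of 0.5 L/h for
#' the healthy 20-30 year-old male reference subject. The central (blood-pool)
#' volume coefficient `v1_per_kg` is a model calibration constant: together
#' with `t_half_dist` it fixes the inter-compartmental clearance, and the
#' elimination half-life is then emergent (about 16.1 h at defaults).
#'
#' @param molecular_weight Molecular weight, g/mol.
#' @param dose_per_kg IV bolus dose, mg/kg.
#' @param cl_ref Typical renal clearance of the reference subject
#'   (74 kg male, GFR 96 mL/min), L/h.
#' @param vss_per_kg Steady-state distribution volume, L/kg.
#' @param v1_per_kg Central (blood-pool) volume, L/kg; calibration constant.
#' @param t_half_dist Distribution-phase half-life, h.
#' @param t_half_elim Elimination-phase half-life, h. Carried for the
#'   macro-parameter inversion [solve_subject_pk()]; the default forward
#'   calibration treats it as emergent.
#' @param kd_albumin Albumin dissociation constant, uM.
#' @param fu_override Optional fixed fraction unbound in (0, 1]; when `NULL`
#'   fu is computed from `kd_albumin` and subject albumin.
#' @param pka_acid,pka_base,logp,psa Physicochemical metadata (acid/base pKa,
#'   octanol-water logP, polar surface area); carried but not used by the
#'   kinetic model.
#' @return An object of class `"compound_params"`.
#' @examples
#' cmp <- compound_params()
#' cmp
#' @export
compound_params <- function(molecular_weight = 975.87,
                            dose_per_kg = 30,
                            cl_ref = 0.5,
                            vss_per_kg = 0.148,
                            v1_per_kg = 0.0545,
                            t_half_dist = 0.48,
                            t_half_elim = 16.3,
                            kd_albumin = 85,
                            fu_override = NULL,
                            pka_acid = 0.78,
                            pka_base = 9.67,
                            logp = -1.2,
                            psa = 268.96) {
  num <- c(molecular_weight = molecular_weight, dose_per_kg = dose_per_kg,
           cl_ref = cl_ref, vss_per_kg = vss_per_kg, v1_per_kg = v1_per_kg,
           t_half_dist = t_half_dist, t_half_elim = t_half_elim,
           kd_albumin = kd_albumin)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all compound parameters must be positive and finite", call. = FALSE)
  if (t_half_dist >= t_half_elim)
    stop("t_half_dist must be smaller than t_half_elim", call. = FALSE)
  if (v1_per_kg >= vss_per_kg)
    stop("v1_per_kg must be smaller than vss_per_kg", call. = FALSE)
  if (!is.null(fu_override)) {
    if (!is.numeric(fu_override) || fu_override <= 0 || fu_override > 1)
      stop("fu_override must lie in (0, 1]", call. = FALSE)
  }
  structure(list(molecular_weight = molecular_weight,
                 dose_per_kg = dose_per_kg,
                 cl_ref = cl_ref,
                 vss_per_kg = vss_per_kg,
                 v1_per_kg = v1_per_kg,
                 t_half_dist = t_half_dist,
                 t_half_elim = t_half_elim,
                 kd_albumin = kd_albumin,
                 fu_override = fu_override,
                 pka_acid = pka_acid, pka_base = pka_base,
                 logp = logp, psa = psa),
            class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat("Contrast-agent compound parameters\n")
  cat(sprintf("  MW %.2f g/mol, dose %g mg/kg IV bolus\n",
              x$molecular_weight, x$dose_per_kg))
  cat(sprintf("  CL(ref) %.3g L/h, Vss %.3g L/kg, V1 %.4g L/kg\n",
              x$cl_ref, x$vss_per_kg, x$v1_per_kg))
  cat(sprintf("  t1/2 dist %.3g h, t1/2 elim %.3g h, Kd(albumin) %g uM\n",
              x$t_half_dist, x$t_half_elim, x$kd_albumin))
  if (!is.null(x$fu_override))
    cat(sprintf("  fu fixed at %.3g\n", x$fu_override))
  invisible(x)
}

#' Fraction unbound in plasma from albumin binding
#'
#' Single-site, ligand-non-saturating binding: with total ligand far below
#' the albumin concentration, `fu = Kd / (Kd + [Alb])`. At the conventional
#' plasma albumin of 45 g/L (677 uM at MW 66,500 g/mol) and Kd = 85 uM this
#' gives fu = 0.11.
#'
#' @param kd Dissociation constant, uM; must be positive.
#' @param albumin_conc Plasma albumin concentration, uM; non-negative.
#' @return Fraction unbound in (0, 1].
#' @examples
#' fraction_unbound(85, albumin_g_per_l_to_um(45))  # ~0.11
#' @export
fraction_unbound <- function(kd, albumin_conc) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be positive", call. = FALSE)
  if (any(albumin_conc < 0))
    stop("albumin_conc must be non-negative", call. = FALSE)
  kd / (kd + albumin_conc)
}

#' Convert plasma albumin from g/L to micromolar
#'
#' @param albumin_g_l Albumin concentration, g/L.
#' @param mw Albumin molecular weight, g/mol (default 66,500).
#' @return Concentration in uM.
#' @export
albumin_g_per_l_to_um <- function(albumin_g_l, mw = 66500) {
  albumin_g_l / mw * 1e6
}

#' Theoretical filtration clearance fu x GFR
#'
#' Renal clearance expected from glomerular filtration alone when only the
#' unbound drug is filtered and there is no secretion or reabsorption.
#'
#' @param fu Fraction unbound in plasma.
#' @param gfr_ml_min Glomerular filtration rate, mL/min.
#' @return Clearance in L/h.
#' @export
filtration_clearance <- function(fu, gfr_ml_min) {
  fu * gfr_ml_min * 60 / 1000
}

#' Macro constants of the two-compartment bolus model
#'
#' Converts micro constants (central volume `v1`, peripheral volume `v2`,
#' inter-compartmental distribution clearance `q`, elimination clearance
#' `cl` acting on the central compartment) into the hybrid rate constants
#' alpha and beta and the bi-exponential coefficients, so that for a bolus
#' dose D the plasma concentration is
#' `C(t) = D * (coeff_a * exp(-alpha t) + coeff_b * exp(-beta t))`.
#'
#' alpha and beta are the roots of `x^2 - (k10+k12+k21) x + k10 k21 = 0`
#' with `k10 = cl/v1`, `k12 = q/v1`, `k21 = q/v2`; `coeff_a + coeff_b = 1/v1`.
#'
#' @param v1,v2 Volumes, L.
#' @param q Inter-compartmental clearance, L/h.
#' @param cl Elimination clearance, L/h.
#' @return List with `alpha`, `beta` (1/h), `coeff_a`, `coeff_b` (per L),
#'   and the micro rate constants `k10`, `k12`, `k21` (1/h).
#' @export
micro_to_macro <- function(v1, v2, q, cl) {
  if (any(c(v1, v2, q, cl) <= 0) || any(!is.finite(c(v1, v2, q, cl))))
    stop("v1, v2, q and cl must be positive", call. = FALSE)
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  # numerically stable quadratic roots: alpha via the large root, beta by Vieta
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- k10 * k21 / alpha
  coeff_a <- (alpha - k21) / (alpha - beta) / v1
  coeff_b <- (k21 - beta) / (alpha - beta) / v1
  list(alpha = alpha, beta = beta, coeff_a = coeff_a, coeff_b = coeff_b,
       k10 = k10, k12 = k12, k21 = k21)
}

#' Inter-compartmental clearance that yields a given distribution rate
#'
#' Solves for the `q` at which the fast hybrid constant of the
#' two-compartment system equals `alpha`, holding `v1`, `v2` and `cl`
#' fixed. Used by the default calibration: `alpha = ln2 / t_half_dist`.
#'
#' @param v1,v2 Volumes, L.
#' @param cl Elimination clearance, L/h.
#' @param alpha Target fast rate constant, 1/h; must exceed `cl/v1`.
#' @return `q` in L/h.
#' @export
q_for_alpha <- function(v1, v2, cl, alpha) {
  k10 <- cl / v1
  if (alpha <= k10)
    stop("alpha must exceed cl/v1 for a positive solution", call. = FALSE)
  denom <- alpha * (1 / v1 + 1 / v2) - k10 / v2
  q <- alpha * (alpha - k10) / denom
  if (!is.finite(q) || q <= 0)
    stop("no positive q solves the requested alpha", call. = FALSE)
  q
}

#' Subject-level structural PK parameter set
#'
#' Constructor for the per-subject two-compartment model: central volume
#' (blood pool), peripheral volume (the single adjusted compartment,
#' representing extravascular-extracellular space), inter-compartmental
#' clearance, renal elimination clearance and fraction unbound. Macro
#' constants are derived on construction.
#'
#' @param v1,v2 Volumes, L.
#' @param q Inter-compartmental clearance, L/h.
#' @param cl_renal Renal elimination clearance, L/h.
#' @param fu Fraction unbound in plasma.
#' @param id Optional subject identifier.
#' @return Object of class `"subject_pk"` with fields `v1`, `v2`, `q_inter`,
#'   `cl_renal`, `fu`, `alpha`, `beta`, `coeff_a`, `coeff_b`.
#' @export
subject_pk <- function(v1, v2, q, cl_renal, fu = NA_real_, id = NA_character_) {
  if (any(c(v1, v2, q, cl_renal) <= 0))
    stop("v1, v2, q and cl_renal must be positive", call. = FALSE)
  m <- micro_to_macro(v1, v2, q, cl_renal)
  structure(list(id = id, v1 = v1, v2 = v2, q_inter = q,
                 cl_renal = cl_renal, fu = fu,
                 alpha = m$alpha, beta = m$beta,
                 coeff_a = m$coeff_a, coeff_b = m$coeff_b),
            class = "subject_pk")
}

#' @export
print.subject_pk <- function(x, ...) {
  cat("Two-compartment subject PK\n")
  cat(sprintf("  V1 %.3f L, V2 %.3f L, Q %.3f L/h, CLr %.3f L/h, fu %.3g\n",
              x$v1, x$v2, x$q_inter, x$cl_renal, x$fu))
  cat(sprintf("  alpha %.4f 1/h (t1/2 %.3f h), beta %.5f 1/h (t1/2 %.2f h)\n",
              x$alpha, log(2) / x$alpha, x$beta, log(2) / x$beta))
  invisible(x)
}

#' Invert macro PK parameters into micro constants
#'
#' Finds the unique positive `(v1, v2, q)` with `v1 + v2 = vss` whose hybrid
#' rate constants match `alpha = ln2/t_half_dist` and `beta = ln2/t_half_elim`
#' at elimination clearance `cl`. Closed form:
#' `v1 = cl^2 / (cl (alpha + beta) - alpha beta vss)`.
#'
#' @param cl Elimination clearance, L/h.
#' @param vss Steady-state volume `v1 + v2`, L.
#' @param t_half_dist Distribution half-life, h.
#' @param t_half_elim Elimination half-life, h (must exceed `t_half_dist`).
#' @param fu Fraction unbound carried into the result.
#' @return A [subject_pk()] object.
#' @export
solve_subject_pk <- function(cl, vss, t_half_dist, t_half_elim, fu = NA_real_) {
  if (any(c(cl, vss, t_half_dist, t_half_elim) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  if (t_half_dist >= t_half_elim)
    stop("infeasible calibration: t_half_dist must be < t_half_elim",
         call. = FALSE)
  alpha <- log(2) / t_half_dist
  beta <- log(2) / t_half_elim
  denom <- cl * (alpha + beta) - alpha * beta * vss
  if (denom <= 0)
    stop("infeasible calibration: cl*(alpha+beta) must exceed alpha*beta*vss ",
         "(no positive central volume exists)", call. = FALSE)
  v1 <- cl^2 / denom
  v2 <- vss - v1
  if (v2 <= 0)
    stop("infeasible calibration: implied central volume exceeds vss ",
         "(peripheral volume would be negative)", call. = FALSE)
  k10 <- cl / v1
  k21 <- alpha * beta / k10
  k12 <- alpha + beta - k10 - k21
  if (k12 <= 0 || k21 <= 0)
    stop("infeasible calibration: implied distribution rate constants are ",
         "not positive", call. = FALSE)
  # internal consistency: q/v2 must equal k21
  q <- k12 * v1
  subject_pk(v1 = v1, v2 = v2, q = q, cl_renal = cl, fu = fu)
}

#' The 74-kg reference healthy subject
#'
#' Builds the default-calibration reference subject: a 74-kg male with GFR
#' 96 mL/min, central volume `v1_per_kg * 74`, peripheral volume
#' `(vss_per_kg - v1_per_kg) * 74`, renal clearance `cl_ref`, and
#' inter-compartmental clearance chosen so the distribution half-life equals
#' `t_half_dist`. The elimination half-life is emergent (~16.1 h).
#'
#' @param compound A [compound_params()] object.
#' @param weight Body weight, kg (default 74).
#' @param albumin_g_l Plasma albumin, g/L (default 45).
#' @return A [subject_pk()] object.
#' @examples
#' ref <- reference_subject()
#' log(2) / ref$beta  # emergent elimination half-life, h
#' @export
reference_subject <- function(compound = compound_params(), weight = 74,
                              albumin_g_l = 45) {
  v1 <- compound$v1_per_kg * weight
  v2 <- (compound$vss_per_kg - compound$v1_per_kg) * weight
  alpha <- log(2) / compound$t_half_dist
  q <- q_for_alpha(v1, v2, compound$cl_ref, alpha)
  fu <- if (!is.null(compound$fu_override)) compound$fu_override
        else fraction_unbound(compound$kd_albumin,
                              albumin_g_per_l_to_um(albumin_g_l))
  subject_pk(v1 = v1, v2 = v2, q = q, cl_renal = compound$cl_ref, fu = fu,
             id = "reference")
}
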