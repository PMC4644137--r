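---
title: "Model and methods behind gadosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gadosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gadosim)
```

## The problem

Gadofosveset is a gadolinium-based blood-pool contrast agent for DCE-MRI
whose reversible binding to serum albumin (Kd = 85 uM) prolongs its vascular
residence. It is eliminated essentially exclusively by the kidneys, so any
condition that alters renal function — renal impairment, the hepatorenal
physiology of cirrhosis, the dosing-by-weight consequences of obesity —
changes its exposure. Clinical PK data in such special populations are
scarce; `gadosim` studies the question with simulated (in-silico) clinical
trials on virtual cohorts, producing the same kinds of outputs a real trial
would: per-subject concentration-time profiles, non-compartmental PK
parameters, and between-cohort statistics.

## Structural model

The agent follows classic bi-compartmental disposition. We use a reduced
minimal-PBPK structure: a central blood-pool compartment (volume $V_1$) and
a single adjusted compartment ($V_{sac}$, volume $V_2$) representing the
extravascular-extracellular space, connected by a distribution clearance
$Q$. Hepatic extraction is zero, which makes the liver/portal loop of the
full minimal-PBPK topology kinetically silent, so the exact two-compartment
reduction applies. Elimination is renal only, from the central compartment:

$$
V_1\frac{dC_1}{dt} = -\left(CL_r + Q\right)C_1 + Q\,C_2,\qquad
V_2\frac{dC_2}{dt} = Q\,(C_1 - C_2).
$$

For an IV bolus dose $D$ the solution is bi-exponential,
$C_1(t) = D\,(A e^{-\alpha t} + B e^{-\beta t})$, with $\alpha,\beta$ the
roots of $x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21}$
($k_{10}=CL_r/V_1$, $k_{12}=Q/V_1$, $k_{21}=Q/V_2$). `gadosim` evaluates
this analytic solution everywhere — concentration, compartment amounts, and
the cumulative urinary amount $CL_r\int_0^t C_1\,ds$ are all closed-form —
so mass balance holds to machine precision and no integrator tolerances
need tuning. A Runge-Kutta integration of the same ODEs exists only as an
independent oracle in the test suite.

### Calibration of the reference subject

The published inputs (CL, $V_{ss}$, both half-lives, Cmax) over-determine a
two-compartment model, so a choice is needed about which to honor exactly.
We prioritise Cmax and the distribution half-life because they anchor the
early profile that DCE-MRI samples:

* $V_1 = 0.0545$ L/kg, chosen so that $C(0^+) = D/V_1 \approx 550$ mg/L for
  a 30 mg/kg dose, matching the reported population Cmax;
* $V_2 = (0.148 - 0.0545)$ L/kg, so $V_1+V_2$ equals the reported $V_{ss}$;
* $Q$ solved in closed form so the fast hybrid root gives
  $t_{1/2,\text{dist}} = 0.48$ h (`q_for_alpha()`);
* $CL_r = 0.5$ L/h for the reference subject (74 kg male, GFR 96 mL/min).

The elimination half-life is then emergent: $\ln 2/\beta \approx 16.1$ h,
within 2% of the reported 16.3 h. (The literature reports both 16.3 h and
18.5 h for this quantity; the default configuration stores 16.3 h and the
config file can override it.) The alternative parameterisation — fix CL,
$V_{ss}$ and both half-lives and let $V_1$ emerge — is available as
`solve_subject_pk()`, which inverts the macro constants exactly:
$V_1 = CL^2/\left(CL(\alpha+\beta) - \alpha\beta V_{ss}\right)$.

### Albumin binding

Binding is single-site and non-saturating (total agent concentration well
below albumin), so $f_u = K_d/(K_d + [\mathrm{Alb}])$, a pure function of
the subject's albumin. At the conventional 45 g/L (677 uM at 66.5 kDa),
$f_u = 0.11$. Importantly, $f_u$ does **not** rescale renal clearance:
predicted and observed clearances sit far below $f_u \times GFR$, and the
observed GFR-clearance relation is a single line across all cohorts
including low-albumin cirrhosis, so clearance is driven by GFR alone and
$f_u$ is carried as a reportable covariate.

## Virtual populations

The published study gives cohort names but no distributions, so the cohort
recipes are design choices of this package, calibrated against the
published cohort-level dose, clearance and AUC means. All continuous
physiology is sampled from truncated normals (inverse-CDF sampling, bounds
at $\pm 3$ SD unless stated); each (seed, cohort, trial, subject)
combination maps deterministically to its own RNG state, so results are
reproducible regardless of execution order.

| cohort | weight (kg) | GFR (mL/min) | albumin (g/L) | v_scale |
|---|---|---|---|---|
| healthy | 73.8 | 108 (sd 12%) | 45 | 1 |
| renal_mod | 70.2 | 59, sd 5, truncated [30, 60] | 45 | 1 |
| renal_sev | 70.2 | 46 (sd 12%) | 45 | 1 |
| obese | 99.9 | 145 | 45 | 0.87 |
| oncology | 74.3 | 96 | 39 | 1 |
| cirrhosis A/B/C | 76.1 | 77 / 79 / 88 | 38 / 31 / 25 | 1.25 / 1.55 / 1.95 |

Rationale for the main choices:

* **Weights** are the published mean cohort dose divided by 30 mg/kg, which
  forces the dose column to match. Per-sex SD is 12 kg with a $\pm 6$ kg
  sex offset; females fill the leading half of each trial
  deterministically, so "half female" is exact at n = 10.
* **GFR means** are back-calculated from the published clearances via the
  linear law $CL_r = 0.5 \cdot GFR/96$ L/h. For `renal_mod` the stated
  30-60 band truncates the upper tail, so the raw mean (59) is set above
  the realized mean (~55.7) that reproduces CL = 0.29 L/h. The `renal_sev`
  effective GFR (46) exceeds its nominal "below 30" label: the published
  severe-cohort CL (0.24 L/h) and AUC fold (2.2) are not consistent with a
  strictly sub-30 GFR under any linear GFR-CL law that also fits the
  healthy cohort, and we prioritise the printed CL/AUC values, keeping the
  label for reporting.
* **`v_scale`** jointly scales $V_1$ and $V_2$. In cirrhosis it implements
  plasma-volume expansion with ascites/edema (1.25/1.55/1.95 by Child-Pugh
  grade), which is the only mechanism in this model that lowers Cmax at a
  fixed mg/kg dose and reproduces the published severity ordering. In
  obesity it is 0.87: vascular volume does not grow proportionally with
  body weight, which raises Cmax as reported. Scaling $V_2$ alone would
  leave $C(0)=D/V_1$ — and hence Cmax — untouched.
* **Inter-individual variability on $V_1$** (log-normal, CV 15%) gives
  Cmax its reported ~15% dispersion; without it Cmax would be a cohort
  constant (dose and $V_1$ both scale with weight) and log-scale ANOVA on
  Cmax would be degenerate. Clearance deliberately carries no extra noise,
  preserving the exact GFR-clearance line.
* **Albumin** declines with cirrhosis severity (standard disease
  physiology) and affects only the reported $f_u$.
* **Ages** are recorded but drive nothing; age-dependent physiology is out
  of scope.

What the generator does *not* emulate: organ-level demography (organ flows
and volumes), creatinine-based GFR equations, assay noise, sampling-time
irregularity, or any correlation between weight, GFR and albumin. Passing
tests therefore demonstrate internal consistency of the model and
calibration, not predictive accuracy for real patients; cohort-level Cmax
and fe for the renal and cirrhosis groups, and all absolute oncology /
cirrhosis values, are reproduced directionally (correct ordering with
severity), not numerically. The cirrhosis urinary-recovery fractions
printed in the source study (0.74/0.60/0.51) are not attainable in a
renal-only two-compartment model at the printed clearances; our fe values
decline monotonically with severity but stay higher.

## Trial engine and NCA

The default design is 10 trials of 10 subjects per cohort, 30 mg/kg IV,
72-h horizon. Pooled statistics are computed over all 100 subjects (the
published SDs are subject-level magnitudes); per-trial means are also
reported. The sampling grid uses 0.05-h steps to 2 h (resolving the 0.48-h
phase) and 0.25-h steps thereafter.

NCA is model-blind: it consumes only (times, concentrations, urine, dose,
weight). Choices, in the absence of stated methods in the source study:

* AUC by linear trapezoid (on these dense analytic grids the log-linear
  alternative differs by <0.1%);
* $\lambda_z$ by least squares on $\ln C$ over the final 24 h, safely past
  the distribution phase;
* reported "AUC" is AUC(0-$\infty$) = AUC(0-last) + $C_{last}/\lambda_z$,
  because the published healthy AUC (4079 mg·h/L) matches mean dose / mean
  CL (~3950) and exceeds any 0-72-h reading across cohorts; both values
  are exported;
* the distribution half-life is recovered by bi-exponential nonlinear
  least squares initialised by curve stripping; profiles without a
  resolvable fast phase (amplitude ratio or rate separation too small) are
  rejected as degenerate rather than silently fitted.

## Statistics

Between-cohort comparison follows the source study's analysis: one-way
ANOVA on log-transformed values with Dunnett many-to-one contrasts against
the healthy control (adjusted p-values from the multivariate-t
distribution, via `multcomp`), significance stars at 0.05/0.01/0.001;
geometric-mean ratios with pooled-variance t confidence intervals on the
log scale; equivalence read against fixed bounds [0.8, 1.2] (the "GMR
± 0.2" rule, implemented as fixed bounds rather than a CI half-width,
following the published forest-plot reference lines); and arithmetic-mean
fold-changes (the published renal fold-increases, 1.8 and 2.2, are ratios
of arithmetic means). Subject-level values are the default analysis unit;
per-trial means are available by flag.

## Numerical notes and problem sizes

The analytic kernel uses the stable quadratic form (large root explicitly,
small root by Vieta) to avoid cancellation when the phases are well
separated. Truncated-normal draws use the inverse-CDF method so each
sample consumes exactly one uniform, keeping the counter-based seeding
stable. Infeasible macro-parameter inversions (no positive central volume)
raise errors naming the violated constraint; volumes and rates are
validated positive throughout.

The shipped examples and tests run the study at its native size (10 x 10
subjects per cohort; a full eight-cohort study takes a few seconds);
Monte-Carlo calibration checks in the tests use a few thousand draws,
which puts standard errors well below the tolerances they check.

## Limitations

No saturable binding, metabolism, transporter kinetics, infusion or
multiple dosing; no blood/plasma partitioning (profiles are plasma); no
crossover designs or dropout; no relaxivity/MRI signal model. The oncology
cohort is directionally calibrated only (AUC ≈ 1.1 x healthy), as the
underlying oncology physiology is not reproduced here.
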