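# gadosim

In-silico clinical trials for the albumin-binding gadolinium blood-pool
contrast agent gadofosveset.

Gadofosveset is eliminated essentially exclusively by the kidneys, so
renal impairment, the hepatorenal physiology of liver cirrhosis, and
weight-based dosing in obesity all modulate its exposure — with
consequences for gadolinium toxicity risk and for the arterial input
functions that DCE-MRI kinetic analysis depends on. Clinical PK data in
these populations are scarce. `gadosim` studies the question by
simulation: virtual cohorts with disease-specific physiology, Monte-Carlo
trial execution, non-compartmental analysis, and the trial-style
between-cohort statistics a clinical pharmacologist would run.

The structural model is a reduced minimal-PBPK two-compartment system — a
central blood pool (volume V1) exchanging with a single adjusted
extravascular-extracellular compartment (V2) through a distribution
clearance Q, with renal-only elimination CLr from the central compartment.
For an IV bolus dose D the plasma concentration is the analytic
bi-exponential

    C(t) = D (A e^{-alpha t} + B e^{-beta t}),

where alpha, beta are the roots of
x^2 − (k10 + k12 + k21) x + k10 k21 with k10 = CLr/V1, k12 = Q/V1,
k21 = Q/V2. Albumin binding enters as a single-site non-saturating law,
fu = Kd/(Kd + [Alb]) (fu = 0.11 at Kd = 85 uM and 45 g/L albumin), and
renal clearance scales linearly with glomerular filtration,
CLr = 0.5 L/h × GFR/96 mL/min. Per-subject profiles are summarised by
standard NCA (Cmax, AUC(0–72), AUC(0–∞), lambda_z, CL, urinary recovery),
and cohorts are compared against healthy controls by log-scale ANOVA with
Dunnett contrasts, geometric-mean ratios with 0.8–1.2 equivalence bounds,
and arithmetic fold-changes.

Eight virtual cohorts ship with the package: `healthy`, `renal_mod` (GFR
30–60 mL/min), `renal_sev`, `obese`, `oncology`, and `cirrhosis_a/b/c`
(Child-Pugh A–C). See the methods vignette
(`vignettes/gadosim-methods.Rmd`) for the calibration of every cohort and
all numerical choices.

## Worked example

```r
library(gadosim)

st <- run_study(trial_design(), "healthy")   # 10 trials x 10 subjects
summary(st)
```

```
Study summary, cohort 'healthy' (n = 100 subjects)
       parameter       mean        sd   n
            dose 2179.40000 380.20000 100
            cmax  554.25000  79.50000 100
        auc_last 3792.90000 786.50000 100
         auc_inf 3941.30000 901.40000 100
          cl_obs    0.56388   0.07100 100
       cl_per_kg    8.05930   2.05900 100
           fe_72    0.96706   0.02176 100
         c_at_1h  253.17000  14.22000 100
 t_half_elim_obs   14.42800   3.08200 100
```

Each row is the pooled mean (SD) over the 100 simulated subjects: the mean
administered dose (mg), peak concentration (mg/L), AUC truncated at 72 h
and extrapolated to infinity (mg·h/L), systemic clearance (L/h and
mL/h/kg), fraction of the dose recovered in urine by 72 h, and the 1-h
concentration. Comparing a renal-impairment cohort against control:

```r
cmp <- compare_cohorts(list(
  healthy   = st,
  renal_sev = run_study(trial_design(), "renal_sev")),
  parameters = c("auc_inf", "cl_obs"))
cmp
```

```
 parameter    cohort control   n geo_mean   gmr ci_low ci_high p_adjusted stars equivalent fold_change
   auc_inf   healthy healthy 100 3830.000 1.000     NA      NA         NA             TRUE       1.000
   auc_inf renal_sev healthy 100 8620.000 2.250  2.100   2.400          0   ***      FALSE       2.240
    cl_obs   healthy healthy 100    0.559 1.000     NA      NA         NA             TRUE       1.000
    cl_obs renal_sev healthy 100    0.238 0.426  0.411   0.441          0   ***      FALSE       0.425
```

Severe renal impairment raises exposure ~2.2-fold with the mirror-image
drop in clearance, far outside the 0.8–1.2 equivalence window and highly
significant under the Dunnett-adjusted test. `plot(st)` draws the semi-log
mean profile with its 5th/95th percentile envelope; `plot(cmp)` draws the
GMR forest plot.

The full eight-cohort replication study — summary table, validation table,
comparison CSV, profile/forest/GFR–CL/urine figures, manifest — is one
call:

```r
run_full_study(default_config(), out_dir = "study_out")
```

A thin command-line wrapper with `study`, `simulate`, `nca` and `compare`
subcommands is installed at `inst/scripts/gadosim`; study parameters can
be overridden with a YAML config (`inst/extdata/default_config.yaml` is
the embedded default).

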