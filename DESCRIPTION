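Package: gadosim
Title: In Silico Clinical Trials for the Blood-Pool Contrast Agent
    Gadofosveset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates intravenous-bolus pharmacokinetics of the
    albumin-binding gadolinium contrast agent gadofosveset in virtual
    population cohorts (healthy volunteers, moderate and severe renal
    impairment, obese, liver cirrhosis Child-Pugh A-C, oncology) using a
    reduced minimal-PBPK two-compartment model with renal-only
    elimination scaled linearly with glomerular filtration rate.
    Provides Monte-Carlo trial execution (trials of subjects with
    cohort-specific physiology), non-compartmental analysis (Cmax, AUC,
    terminal half-life, clearance, urinary recovery), and between-cohort
    comparison by log-scale ANOVA with Dunnett many-to-one contrasts,
    geometric-mean ratios with equivalence bounds, and arithmetic
    fold-changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    multcomp,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
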