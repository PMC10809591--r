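Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling with Parametric
    Survival Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three-state partitioned survival modelling for oncology
    cost-effectiveness analysis: parametric survival extrapolation from
    individual-patient data or digitized Kaplan-Meier curves with AIC/BIC
    model selection, Guyot-style pseudo-IPD reconstruction, a 21-day-cycle
    cohort engine with discounting, half-cycle correction and
    background-mortality hazard blending, cost and QALY accrual with
    incremental cost-effectiveness ratios, one-way and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and
    scenario analysis (drug-donation payment schedules, price reductions,
    alternate discount rates). Ships a calibrated two-strategy model of
    pembrolizumab versus chemotherapy in platinum-pretreated recurrent or
    metastatic nasopharyngeal carcinoma, plus a synthetic trial-data
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
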