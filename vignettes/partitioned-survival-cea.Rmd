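---
title: "Methods: partitioned-survival cost-effectiveness modelling with psmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness modelling with psmcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The model and its assumptions

`psmcea` implements a three-state partitioned survival model (PSM) for
two-strategy oncology cost-effectiveness analysis. Unlike a Markov
state-transition model, a PSM does not specify transition rates: at each
evaluation time the cohort is partitioned directly from two survival
curves,

* progression-free: `min(S_PFS(t), S_OS(t))`,
* dead: `1 - S_OS(t)`,
* progressed disease: the remainder,

so the three memberships sum to one by construction. The implicit
assumptions are the standard PSM ones: the curves summarise all relevant
history (no tunnel effects), progression is irreversible, and the PFS and
OS curves jointly describe the same cohort. Because the two curves are
fitted (or calibrated) independently, they can cross; the engine clamps
PFS at OS cycle by cycle and emits a warning naming the crossed range. In
the shipped base case a small crossing occurs in the first cycle, where a
lognormal PFS curve is still nearly flat while an exponential OS curve
falls immediately — an artefact of the independent parametric forms, not
of the data.

The shipped configuration models pembrolizumab versus mixed chemotherapy
(capecitabine, gemcitabine, docetaxel) in platinum-pretreated recurrent or
metastatic nasopharyngeal carcinoma, with all costs in 2022 US dollars.

## Time grid, discounting, half-cycle correction

Time is handled internally in days (1 month = 365.25/12 = 30.4375 days;
this matters because cycle length is quoted in days, medians in months and
the horizon in years). The default grid is 21-day cycles over 5 years.
Five years is 86.96 cycles; the count is rounded *up* to 87 full cycles so
no survival benefit inside the stated horizon is truncated (rounding down
would shorten the horizon by most of a cycle).

Half-cycle correction is implemented as midpoint evaluation: memberships
and discount factors are taken at `t_k = (k - 1/2) * 21` days. This is the
standard continuous-approximation equivalent of adding/removing half
cycles at the ends, and it applies uniformly to costs and effects.
Discounting is continuous-equivalent, `1/(1+r)^(t/365.25)` with `r = 0.05`
per year by default (range 0–8% in sensitivity and scenario analyses).

## Survival inputs

Each arm/endpoint accepts one of three input modes:

1. **Published medians** (the default base case): an exponential curve is
   calibrated as `rate = ln 2 / median` and a lognormal as
   `meanlog = ln(median)` with a supplied `sdlog`; either way
   `S(median) = 0.5` exactly. The base case uses OS medians 17.2 / 15.3
   months (exponential) and PFS medians 4.1 / 5.5 months (lognormal,
   `sdlog = 1.0`). The lognormal spread is not identified by a median
   alone; 1.0 is a typical fitted value for progression endpoints and is a
   named configuration field so its influence can be explored.
2. **Individual patient data** (CSV): all six families — exponential,
   Weibull, log-logistic, lognormal, Gompertz, generalized gamma — are fit
   by maximum likelihood under right censoring via `flexsurv`, and the
   AIC-minimising converged fit is selected. `BIC` (with n = subjects, the
   common convention) is also reported. Ties are broken toward fewer
   parameters, then alphabetically, so selection is reproducible.
3. **Digitized Kaplan–Meier coordinates** (CSV): pseudo-IPD are first
   reconstructed with an interval-wise Guyot-type algorithm — events are
   recovered by inverting the product-limit identity over the digitized
   drops; with a numbers-at-risk table, censorings are allocated uniformly
   within each risk interval and adjusted iteratively to match the
   at-risk counts; without one, censoring is assumed only at the end of
   follow-up. The reconstruction round-trips the digitized curve to well
   under 0.02 sup-norm in the tests.

On the generalized gamma (location–scale–shape form), the shape parameter
`Q = 0` is the lognormal limit; evaluations switch to the lognormal
formula for `|Q| < 1e-5` to avoid the numerical instability near that
interior point.

A note on AIC selection consistency: because Weibull, Gompertz and
generalized gamma all nest the exponential, AIC — whose penalty is fixed
at 2 per parameter — picks one of the larger families for
exponential-generated data with asymptotic probability around 25–35%
(union of correlated chi-square exceedances). Selection rates above ~75%
for a true exponential are therefore not achievable with this candidate
set under AIC; BIC, whose penalty grows with `log n`, is near-consistent
and is the better criterion when parsimony matters. Both are reported.

## Background mortality

General-population mortality enters as a hazard floor on OS:
`h*(t) = max(h_model(t), h_background(age_0 + t))`, integrated on a daily
grid. The floor (rather than an additive hazard) is the conservative
reading: the modelled OS curve already contains all-cause deaths for the
trial population, so adding background hazard would double-count except
where extrapolation drives the model hazard below that of the general
population. The cohort starting age defaults to 50 and is configurable.
The packaged life table is *synthetic* (Gompertz–Makeham shaped, ages
0–100, file `life_table_synthetic.csv`); it stands in for a national
table so the mechanism is runnable and testable, and at ages 50–60 its
hazard (~0.4–0.9%/yr) is far below the disease hazard of the base case
(~50%/yr), so the floor is inactive there by design.

## Costs, utilities, accrual

Per-cycle drug costs: pembrolizumab $5,327.90; the chemotherapy arm
defaults to the equal-weight mean of capecitabine ($36.39), gemcitabine
($44.16) and docetaxel ($31.22) — the mixing weights are configurable
because no published split exists. Pembrolizumab treatment is capped at 35
cycles; chemotherapy treats to progression. Drug cost accrues against the
on-treatment occupancy (PFS membership up to the cap).

Serious adverse events (grade ≥ 3 anemia, $6,562.68; neutrocytopenia,
$475.32) are costed once, at cycle 1, as incidence × unit cost
(pembrolizumab 0.9%/0%; chemotherapy 10.7%/27.7%) — consistent with the
assumption that such events cluster at treatment initiation. AE
disutilities and AE-driven discontinuation are deliberately out of scope.

Monitoring: laboratory tests ($11.89) every cycle and imaging ($207.25)
every third cycle, both scaled by the alive membership; the schedule is
configurable since only the unit charges, not frequencies, are published.
Terminal care ($1,460.30) attaches to the new-deaths increment of each
cycle and is discounted at that cycle. Utilities are 0.76 (PFS), 0.35
(PD), 0 (dead), so QALY ≤ LY always.

## Sensitivity analysis

Published ranges are read as 95% intervals, `SD = (high - low)/3.92`;
parameters without a range (the AE incidences) use ±20% of base. One-way
analysis re-evaluates the model at each bound with everything else at
base and orders rows by ICER span; because an ICER is unstable when the
incremental QALY passes through zero (which the utility parameters can
cause here), incremental-NMB columns are reported alongside.

The PSA samples gamma distributions for costs (shape = mean²/SD²,
scale = SD²/mean) and betas for utilities and incidences
(`alpha = mean(mean(1-mean)/SD² - 1)`), matched to mean = base; a zero
width yields a point mass. Parameters are drawn independently — no
correlation structure is published — and survival parameters are held
fixed as structural. The discount rate is likewise structural and
excluded from the PSA by default (a flag re-enables it as a beta on
0–8%): sampling a discount rate mixes preference uncertainty into
parameter uncertainty, which is conventionally handled in scenarios
instead. 1000 iterations is the default. The CEAC reports, per
willingness-to-pay value, the fraction of iterations with positive
incremental net monetary benefit.

## Scenario analyses

* **Donation program**: patients pay cycles 1–2 and 5–6 and receive
  cycles 3–4 and 7–35 free, stopping at progression or 35 cycles. A
  "course" is interpreted as one 21-day cycle, and the schedule is applied
  expectation-wise to cohort occupancy (paid cycles × occupancy ×
  discount), not per simulated individual.
* **Price reduction**: the reference drug price is scaled by `1 - f`
  (default f = 0.6), leaving every other component untouched.
* **Discount rates**: full re-run at 3% and 8% annual discount.

## The synthetic trial generator

`simulate_trial()` emulates a two-arm trial shaped like the base case: OS
exponential (medians 17.2/15.3 months), PFS lognormal (medians 4.1/5.5
months, `sdlog` 1.0), uniform accrual over a year, administrative cutoff
at 5 years, default 100 subjects per arm (arm sizes are configurable; no
published censoring pattern exists to copy). Latent PFS and OS times
share a Gaussian copula with correlation 0.95 and PFS is truncated at OS
— PFS ends at progression *or death*, so truncation is definitionally
required, and the strong positive dependence keeps the marginal PFS
median at its target (with independent draws, truncation would drag the
PFS KM median from 5.5 to roughly 4.2 months). What the generator does
*not* emulate: covariates, subgroups, response endpoints, loss to
follow-up, or non-proportional late effects such as immunotherapy
survival plateaus. Tests passing on these data therefore validate the
pipeline's statistics, not the clinical realism of any particular
extrapolation.

## Numerical choices and degenerate inputs

* Cycle-count ceiling uses a 1e-9 tolerance so an exactly integer number
  of cycles is not inflated by floating-point noise.
* Background-mortality integration uses a 1-day grid with exact
  `-d log S` increments for the model hazard.
* Curve crossings (PFS > OS) are clamped with a warning; memberships are
  clamped to [0, 1]; new-death increments are floored at 0.
* Flat digitized curves (no events), all-censored datasets, zero-width
  parameter ranges, zero cutoffs and empty WTP grids are all rejected (or
  degenerate to point masses) with explicit errors rather than silently.
* Optimizer failures in fitting are retried from jittered starts (up to
  two restarts) and surfaced as `converged = FALSE`, never dropped
  silently; selection uses converged fits only.

## Problem sizes used by the test suite

Parameter-recovery properties run 50 replicates per family at n = 1000
with ~20% administrative censoring; selection-consistency properties run
50 replicates at n = 1000; Kaplan–Meier agreement uses n = 5000; sampler
moment checks use 10,000 draws; the probabilistic analysis uses the
default 1000 iterations. These sizes make the statistical assertions
sharp while keeping a full run of the suite fast on a single core.

## Known limitations

* The published base-case totals cannot be reproduced exactly from public
  information: the fitted survival parameters behind the original
  analysis and its monitoring schedule are not published, so this package
  calibrates curves from the printed medians instead. The calibrated base
  case yields a higher pembrolizumab cost and a slightly *negative*
  incremental QALY (the pembrolizumab arm's shorter PFS median outweighs
  its OS advantage at the published utilities) — the strategy is
  dominated rather than merely above the threshold, and the headline
  probabilistic conclusion (0% probability of cost-effectiveness at
  $38,223.34/QALY) is identical and robust: the incremental cost is an
  order of magnitude larger than any attainable QALY gain valued at the
  threshold.
* No spline or cure-fraction models, no covariate adjustment, no
  value-of-information analysis, no survival-parameter uncertainty in the
  PSA (no published basis for it).
* The donation-program accounting follows the published schedule text;
  the original scenario's printed totals imply a different (unstated)
  accounting and are not asserted.
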