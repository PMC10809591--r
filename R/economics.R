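#' Continuous-time discount factor
#'
#' `1 / (1 + rate)^(t / 365.25)` for time `t` in days.
#'
#' @param t_days Times in days (>= 0).
#' @param annual_rate Annual discount rate (> -1).
#' @return Discount factors.
#' @examples
#' discount_factor(365.25, 0.05)  # 1/1.05 = 0.952381
#' @export
discount_factor <- function(t_days, annual_rate) {
  if (any(t_days < 0)) stop("t must be non-negative")
  if (annual_rate <= -1) stop("annual rate must exceed -1")
  1 / (1 + annual_rate)^(t_days / DAYS_PER_YEAR)
}

#' Strategy cost inputs
#'
#' Per-cycle and event costs (2022 USD) for one treatment strategy. For a
#' mixed chemotherapy arm, supply `chemo_mix` — a data frame with columns
#' `drug`, `cost_per_cycle`, `weight` (weights summing to 1) — and the
#' per-cycle drug cost is the weighted mean.
#'
#' @param name Strategy label.
#' @param drug_cost_per_cycle Drug cost per 21-day cycle (USD); ignored when
#'   `chemo_mix` is given.
#' @param chemo_mix Optional regimen mix (see above).
#' @param ae_events Data frame with columns `name`, `probability`,
#'   `unit_cost`: serious adverse events costed once, at model start, as
#'   probability x unit cost.
#' @param imaging_cost,lab_cost Cost per imaging / laboratory event (USD).
#' @param imaging_interval,lab_interval Scheduling in cycles (an event every
#'   so many cycles, while alive).
#' @param terminal_care_cost One-time cost attached to each death (USD).
#' @param treatment_cap Maximum treated cycles, or `NULL` (uncapped).
#' @return A list of class `strategy_inputs`.
#' @export
strategy_inputs <- function(name, drug_cost_per_cycle = 0, chemo_mix = NULL,
                            ae_events = NULL,
                            imaging_cost = 207.25, lab_cost = 11.89,
                            imaging_interval = 3, lab_interval = 1,
                            terminal_care_cost = 1460.30,
                            treatment_cap = NULL) {
  if (!is.null(chemo_mix)) {
    stopifnot(all(c("drug", "cost_per_cycle", "weight") %in%
                    names(chemo_mix)))
    if (abs(sum(chemo_mix$weight) - 1) > 1e-9) {
      stop("chemo mix weights must sum to 1")
    }
    drug_cost_per_cycle <- sum(chemo_mix$cost_per_cycle * chemo_mix$weight)
  }
  if (is.null(ae_events)) {
    ae_events <- data.frame(name = character(), probability = numeric(),
                            unit_cost = numeric())
  }
  costs <- c(drug_cost_per_cycle, ae_events$unit_cost, imaging_cost,
             lab_cost, terminal_care_cost)
  if (any(costs < 0)) stop("costs must be non-negative")
  if (any(ae_events$probability < 0) || any(ae_events$probability > 1)) {
    stop("AE probabilities must lie in [0, 1]")
  }
  structure(list(name = name, drug_cost_per_cycle = drug_cost_per_cycle,
                 chemo_mix = chemo_mix, ae_events = ae_events,
                 imaging_cost = imaging_cost, lab_cost = lab_cost,
                 imaging_interval = imaging_interval,
                 lab_interval = lab_interval,
                 terminal_care_cost = terminal_care_cost,
                 treatment_cap = treatment_cap),
            class = "strategy_inputs")
}

#' Health-state utilities
#'
#' @param u_pfs Utility while progression-free (default 0.76).
#' @param u_pd Utility after progression (default 0.35).
#' @param u_dead Utility when dead (0).
#' @return A list of class `utility_inputs`.
#' @export
utility_inputs <- function(u_pfs = 0.76, u_pd = 0.35, u_dead = 0) {
  if (!(0 <= u_dead && u_dead <= u_pd && u_pd <= u_pfs && u_pfs <= 1)) {
    stop("need 0 <= u_dead <= u_pd <= u_pfs <= 1")
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd, u_dead = u_dead),
            class = "utility_inputs")
}

#' Accrue discounted costs over a trace
#'
#' Components, all discounted at the trace's per-cycle factors:
#' \itemize{
#'   \item drug: per-cycle price x on-treatment occupancy;
#'   \item adverse events: `sum(probability * unit_cost)` applied once at
#'     cycle 1 (serious events are assumed to occur at treatment start);
#'   \item monitoring: laboratory and imaging events on their schedules,
#'     scaled by the alive (PFS + PD) membership;
#'   \item terminal care: unit cost x new deaths each cycle.
#' }
#'
#' @param trace A `psm_trace` (treatment cap already applied, or applied
#'   here via `inputs$treatment_cap`).
#' @param inputs A [strategy_inputs()].
#' @param plan The [build_cycle_plan()] the trace was built from.
#' @return List with `total` and a `breakdown` vector
#'   (`drug`, `ae`, `monitoring`, `terminal`).
#' @export
accrue_costs <- function(trace, inputs, plan) {
  stopifnot(inherits(trace, "psm_trace"), inherits(inputs, "strategy_inputs"),
            inherits(plan, "cycle_plan"))
  if (nrow(trace) != plan$n_cycles) {
    stop("trace and cycle plan lengths differ")
  }
  trace <- on_treatment_occupancy(trace, inputs$treatment_cap)
  d <- trace$discount_factor
  k <- trace$cycle
  alive <- trace$pfs + trace$pd

  drug <- sum(inputs$drug_cost_per_cycle * trace$on_treatment * d)
  ae_lump <- sum(inputs$ae_events$probability * inputs$ae_events$unit_cost)
  ae <- ae_lump * d[1]
  lab_due <- as.numeric(k %% max(1, inputs$lab_interval) == 0)
  img_due <- as.numeric(k %% max(1, inputs$imaging_interval) == 0)
  monitoring <- sum((inputs$lab_cost * lab_due +
                     inputs$imaging_cost * img_due) * alive * d)
  terminal <- sum(inputs$terminal_care_cost * trace$new_deaths * d)

  breakdown <- c(drug = drug, ae = ae, monitoring = monitoring,
                 terminal = terminal)
  list(total = sum(breakdown), breakdown = breakdown)
}

#' Accrue discounted life-years and QALYs over a trace
#'
#' `LY = sum((pfs + pd) * dt_years * d)` and
#' `QALY = sum((u_pfs * pfs + u_pd * pd) * dt_years * d)` with `dt_years`
#' the cycle length in years.
#'
#' @inheritParams accrue_costs
#' @param utilities A [utility_inputs()].
#' @return List with `ly` and `qaly` (discounted).
#' @export
accrue_effects <- function(trace, utilities, plan) {
  stopifnot(inherits(trace, "psm_trace"),
            inherits(utilities, "utility_inputs"),
            inherits(plan, "cycle_plan"))
  if (nrow(trace) != plan$n_cycles) {
    stop("trace and cycle plan lengths differ")
  }
  dt_years <- plan$cycle_length_days / DAYS_PER_YEAR
  d <- trace$discount_factor
  ly <- sum((trace$pfs + trace$pd) * dt_years * d)
  qaly <- sum((utilities$u_pfs * trace$pfs + utilities$u_pd * trace$pd) *
                dt_years * d)
  list(ly = ly, qaly = qaly)
}

#' Strategy totals
#'
#' @param name Strategy label.
#' @param cost,ly,qaly Discounted totals.
#' @return A list of class `strategy_totals`.
#' @export
strategy_totals <- function(name, cost, ly, qaly) {
  structure(list(name = name, cost = cost, ly = ly, qaly = qaly),
            class = "strategy_totals")
}

#' Incremental cost-effectiveness result
#'
#' Incrementals are reference minus comparator. The ICER is reported when
#' the corresponding effect difference is non-zero; dominance is classified
#' on the QALY scale (dominant: cheaper and more effective; dominated:
#' costlier and less effective). With zero effect difference, the ICER is
#' undefined (`NA`) and dominance follows cost alone.
#'
#' @param reference,comparator [strategy_totals()] for the intervention and
#'   its comparator.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A list of class `ce_result`: per-strategy totals, `inc_cost`,
#'   `inc_ly`, `inc_qaly`, `icer_per_ly`, `icer_per_qaly`, `dominance`,
#'   `cost_effective`, `wtp`.
#' @examples
#' chemo <- strategy_totals("chemotherapy", 2734.55, 3.93, 2.73)
#' pembro <- strategy_totals("pembrolizumab", 39710.96, 3.96, 2.82)
#' compute_icer(pembro, chemo, wtp = 38223.34)
#' @export
compute_icer <- function(reference, comparator, wtp = 38223.34) {
  stopifnot(inherits(reference, "strategy_totals"),
            inherits(comparator, "strategy_totals"))
  inc_cost <- reference$cost - comparator$cost
  inc_ly <- reference$ly - comparator$ly
  inc_qaly <- reference$qaly - comparator$qaly
  icer_ly <- if (!is.na(inc_ly) && inc_ly != 0) {
    inc_cost / inc_ly
  } else {
    NA_real_  # NA life-years (not modelled) or zero difference
  }
  icer_q <- if (inc_qaly != 0) inc_cost / inc_qaly else NA_real_
  dominance <- if (inc_qaly > 0 && inc_cost < 0) {
    "dominant"
  } else if (inc_qaly < 0 && inc_cost > 0) {
    "dominated"
  } else if (inc_qaly == 0 && inc_cost != 0) {
    if (inc_cost < 0) "dominant" else "dominated"  # dominance by cost
  } else {
    "none"
  }
  cost_effective <- dominance == "dominant" ||
    (inc_qaly > 0 && !is.na(icer_q) && icer_q <= wtp)
  structure(list(strategies = data.frame(
                   name = c(reference$name, comparator$name),
                   cost = c(reference$cost, comparator$cost),
                   ly = c(reference$ly, comparator$ly),
                   qaly = c(reference$qaly, comparator$qaly),
                   stringsAsFactors = FALSE),
                 inc_cost = inc_cost, inc_ly = inc_ly, inc_qaly = inc_qaly,
                 icer_per_ly = icer_ly, icer_per_qaly = icer_q,
                 dominance = dominance, cost_effective = cost_effective,
                 wtp = wtp),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  print(transform(x$strategies, cost = round(cost, 2), ly = round(ly, 3),
                  qaly = round(qaly, 3)))
  cat(sprintf("  Incr cost: %.2f  Incr LY: %.4f  Incr QALY: %.4f\n",
              x$inc_cost, x$inc_ly, x$inc_qaly))
  cat(sprintf("  ICER/LY: %s  ICER/QALY: %s  dominance: %s\n",
              format(round(x$icer_per_ly, 2)),
              format(round(x$icer_per_qaly, 2)), x$dominance))
  cat(sprintf("  Cost-effective at WTP %.2f: %s\n", x$wtp,
              x$cost_effective))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * QALY - cost` for a strategy;
#' `incremental NMB = wtp * inc_QALY - inc_cost` for a `ce_result`.
#'
#' @param x A [strategy_totals()] or [compute_icer()] result.
#' @param wtp Willingness-to-pay (USD/QALY, >= 0).
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(x, wtp) {
  if (wtp < 0) stop("wtp must be non-negative")
  if (inherits(x, "strategy_totals")) return(wtp * x$qaly - x$cost)
  if (inherits(x, "ce_result")) return(wtp * x$inc_qaly - x$inc_cost)
  stop("x must be strategy_totals or ce_result")
}
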