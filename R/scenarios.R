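#' Philanthropic drug-donation payment schedule
#'
#' The assistance program modelled: patients self-fund cycles 1-2, receive
#' cycles 3-4 as donation, self-fund cycles 5-6, then receive the drug free
#' until progression or 35 total cycles. Only the paid cycles generate drug
#' cost; no drug is given beyond the cap.
#'
#' @param paid_cycles Cycles the patient pays for (default `c(1, 2, 5, 6)`).
#' @param donated_cycles Donated cycles (default `c(3, 4, 7:35)`).
#' @param cap_cycles Maximum treated cycles (default 35).
#' @return A list of class `donation_schedule`.
#' @export
donation_schedule <- function(paid_cycles = c(1, 2, 5, 6),
                              donated_cycles = c(3, 4, 7:35),
                              cap_cycles = 35) {
  if (length(intersect(paid_cycles, donated_cycles))) {
    stop("paid and donated cycles must be disjoint")
  }
  if (any(c(paid_cycles, donated_cycles) > cap_cycles)) {
    stop("all schedule indices must be <= the treatment cap")
  }
  structure(list(paid_cycles = as.integer(paid_cycles),
                 donated_cycles = as.integer(donated_cycles),
                 cap_cycles = as.integer(cap_cycles)),
            class = "donation_schedule")
}

#' Discounted drug cost under a donation schedule
#'
#' `cost = sum over paid cycles of price x on-treatment occupancy x
#' discount factor`; donated cycles contribute nothing. Applied
#' expectation-wise to the cohort occupancy.
#'
#' @param trace A `psm_trace` (with the schedule's cap applied to
#'   `on_treatment`; it is re-applied here).
#' @param price_per_cycle Drug price per cycle (USD).
#' @param schedule A [donation_schedule()].
#' @param plan The model's [build_cycle_plan()].
#' @return Discounted drug cost (USD).
#' @export
donation_drug_cost <- function(trace, price_per_cycle, schedule, plan) {
  stopifnot(inherits(trace, "psm_trace"),
            inherits(schedule, "donation_schedule"),
            inherits(plan, "cycle_plan"))
  trace <- on_treatment_occupancy(trace, schedule$cap_cycles)
  paid <- trace$cycle %in% schedule$paid_cycles
  sum(price_per_cycle * trace$on_treatment[paid] *
        trace$discount_factor[paid])
}

#' Scale a strategy's drug price down by a fraction
#'
#' @param inputs A [strategy_inputs()].
#' @param fraction Price reduction in `[0, 1]` (0.6 = 60% cheaper).
#' @return The inputs with `drug_cost_per_cycle` scaled by
#'   `(1 - fraction)`; all other fields unchanged.
#' @export
apply_price_reduction <- function(inputs, fraction) {
  stopifnot(inherits(inputs, "strategy_inputs"))
  if (fraction < 0 || fraction > 1) {
    stop("price-reduction fraction must lie in [0, 1]")
  }
  inputs$drug_cost_per_cycle <- inputs$drug_cost_per_cycle * (1 - fraction)
  inputs
}

#' Default scenario list
#'
#' The three scenario analyses of the shipped model: the philanthropic
#' donation program, a 60% drug-price reduction, and 3% / 8% annual
#' discount rates.
#'
#' @return A list of scenario definitions for [run_scenarios()].
#' @export
default_scenarios <- function() {
  list(
    list(name = "philanthropic drug donation program", type = "donation"),
    list(name = "price dropped by 60%", type = "price_reduction",
         fraction = 0.6),
    list(name = "3% discount", type = "discount", rate = 0.03),
    list(name = "8% discount", type = "discount", rate = 0.08))
}

evaluate_donation_scenario <- function(model, schedule) {
  base <- evaluate_model(model)
  ref <- model$config$reference
  trace <- model$traces[[ref]]
  price <- model$config$costs$pembrolizumab_cycle
  inputs <- strategy_inputs_from_config(model$config, ref)
  full <- accrue_costs(trace, inputs, model$plan)
  don_drug <- donation_drug_cost(trace, price, schedule, model$plan)
  new_cost <- full$total - full$breakdown[["drug"]] + don_drug
  st <- base$strategies
  ref_tot <- strategy_totals(ref, new_cost, st$ly[st$name == ref],
                             st$qaly[st$name == ref])
  comp <- model$config$comparator
  comp_tot <- strategy_totals(comp, st$cost[st$name == comp],
                              st$ly[st$name == comp],
                              st$qaly[st$name == comp])
  compute_icer(ref_tot, comp_tot, wtp = model$config$wtp)
}

#' Run scenario analyses
#'
#' Each scenario re-runs the two-strategy model under one transform:
#' `"donation"` (reference drug cost follows [donation_schedule()]),
#' `"price_reduction"` (reference drug price scaled by `1 - fraction`), or
#' `"discount"` (annual discount overridden by `rate`). The base case is
#' always included as the first row pair.
#'
#' @param config A [default_config()]-shaped list.
#' @param scenarios List of scenario definitions ([default_scenarios()]);
#'   an empty list yields the base case only.
#' @param model Optional pre-built model (avoids rebuilding).
#' @return A data frame shaped like a published scenario table: one row per
#'   strategy per scenario with `scenario`, `strategy`, `cost`, `incr_cost`,
#'   `eff` (QALYs), `incr_eff`, `icer`, `remarks`.
#' @export
run_scenarios <- function(config = default_config(),
                          scenarios = default_scenarios(),
                          model = NULL) {
  model <- model %||% build_model(config)
  results <- list(list(name = "base case", res = evaluate_model(model)))
  for (sc in scenarios) {
    res <- switch(sc$type,
      donation = evaluate_donation_scenario(
        model, sc$schedule %||% donation_schedule()),
      price_reduction = {
        m2 <- model
        m2$config$costs$pembrolizumab_cycle <-
          model$config$costs$pembrolizumab_cycle * (1 - sc$fraction)
        if (sc$fraction < 0 || sc$fraction > 1) {
          stop("price-reduction fraction must lie in [0, 1]")
        }
        evaluate_model(m2)
      },
      discount = evaluate_model(model, list(discount_rate = sc$rate)),
      stop("unknown scenario type: '", sc$type, "'")
    )
    results <- c(results, list(list(name = sc$name, res = res)))
  }
  rows <- lapply(results, function(x) {
    st <- x$res$strategies
    comp_i <- which(st$name == model$config$comparator)
    ref_i <- which(st$name == model$config$reference)
    data.frame(
      scenario = x$name,
      strategy = st$name[c(comp_i, ref_i)],
      cost = round(st$cost[c(comp_i, ref_i)], 2),
      incr_cost = c(NA, round(x$res$inc_cost, 2)),
      eff = round(st$qaly[c(comp_i, ref_i)], 2),
      incr_eff = c(NA, round(x$res$inc_qaly, 2)),
      icer = c(NA, round(x$res$icer_per_qaly, 2)),
      remarks = c("", x$res$dominance),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
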