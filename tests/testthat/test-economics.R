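test_that("discount factors follow 1/(1+r)^(t/365.25)", {
  expect_equal(discount_factor(365.25, 0.05), 1 / 1.05)
  expect_equal(discount_factor(365.25, 0.05), 0.952381, tolerance = 1e-6)
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(c(100, 5000), 0), c(1, 1))
  expect_error(discount_factor(-1, 0.05), "non-negative")
  expect_error(discount_factor(10, -1.5), "exceed")
})

test_that("chemotherapy mix collapses to a weighted per-cycle cost", {
  mix <- data.frame(drug = c("capecitabine", "gemcitabine", "docetaxel"),
                    cost_per_cycle = c(36.39, 44.16, 31.22),
                    weight = rep(1 / 3, 3))
  si <- strategy_inputs("chemotherapy", chemo_mix = mix)
  expect_equal(si$drug_cost_per_cycle, (36.39 + 44.16 + 31.22) / 3)
  mix$weight <- c(0.5, 0.5, 0.5)
  expect_error(strategy_inputs("x", chemo_mix = mix), "sum to 1")
  expect_error(strategy_inputs("x", drug_cost_per_cycle = -5),
               "non-negative")
  expect_error(utility_inputs(0.3, 0.5), "u_pd <= u_pfs")
})

test_that("adverse-event lump sums match hand arithmetic", {
  plan <- build_cycle_plan(annual_discount = 0)
  empty <- make_trace(rep(0, 87), rep(0, 87), rep(0, 87))
  chemo <- strategy_inputs(
    "chemotherapy", drug_cost_per_cycle = 37.2567,
    ae_events = data.frame(name = c("anemia", "neutrocytopenia"),
                           probability = c(0.107, 0.277),
                           unit_cost = c(6562.68, 475.32)))
  cost <- accrue_costs(empty, chemo, plan)
  expect_equal(cost$breakdown[["ae"]],
               0.107 * 6562.68 + 0.277 * 475.32)  # 833.87
  expect_equal(cost$breakdown[["ae"]], 833.87, tolerance = 1e-5)
  # zero-membership trace: only the cycle-1 AE lump accrues
  expect_equal(cost$total, cost$breakdown[["ae"]])

  pembro <- strategy_inputs(
    "pembrolizumab", drug_cost_per_cycle = 5327.90,
    ae_events = data.frame(name = c("anemia", "neutrocytopenia"),
                           probability = c(0.009, 0),
                           unit_cost = c(6562.68, 475.32)))
  cost_p <- accrue_costs(empty, pembro, plan)
  expect_equal(cost_p$breakdown[["ae"]], 0.009 * 6562.68)  # 59.06
  expect_equal(cost_p$breakdown[["ae"]], 59.06, tolerance = 1e-3)
})

test_that("cost components accrue against occupancy and deaths", {
  plan <- build_cycle_plan(annual_discount = 0)
  # half the cohort progression-free throughout, one death wave at cycle 2
  dead <- c(0, rep(0.2, 86))
  tr <- make_trace(rep(0.5, 87), pmax(0, 1 - 0.5 - dead), dead)
  si <- strategy_inputs("x", drug_cost_per_cycle = 100,
                        imaging_cost = 30, lab_cost = 10,
                        imaging_interval = 3, lab_interval = 1,
                        terminal_care_cost = 1000,
                        treatment_cap = 10)
  cost <- accrue_costs(tr, si, plan)
  expect_equal(cost$breakdown[["drug"]], 100 * 0.5 * 10)
  alive <- tr$pfs + tr$pd
  expect_equal(cost$breakdown[["monitoring"]],
               sum((10 + 30 * (tr$cycle %% 3 == 0)) * alive))
  expect_equal(cost$breakdown[["terminal"]], 1000 * 0.2)
  expect_error(accrue_costs(make_trace(1, 0, 0), si, plan), "differ")
})

test_that("one undiscounted cycle in PFS yields the hand-computed LY/QALY", {
  plan <- build_cycle_plan(horizon_years = 21 / 365.25,
                           cycle_length_days = 21, annual_discount = 0)
  expect_equal(plan$n_cycles, 1L)
  tr <- make_trace(1, 0, 0)
  eff <- accrue_effects(tr, utility_inputs(0.76, 0.35), plan)
  expect_equal(eff$ly, 21 / 365.25)          # 0.0575 years
  expect_equal(eff$qaly, 0.76 * 21 / 365.25) # 0.0437
  # all-dead trace accrues nothing
  eff0 <- accrue_effects(make_trace(0, 0, 1), utility_inputs(), plan)
  expect_equal(eff0$ly, 0)
  expect_equal(eff0$qaly, 0)
})

test_that("ICER arithmetic, dominance and degenerate cases", {
  tot <- printed_totals()
  res <- compute_icer(tot$pembro, tot$chemo, wtp = 38223.34)
  expect_equal(res$inc_cost, 36976.41)
  expect_equal(res$inc_qaly, 0.09)
  expect_equal(res$icer_per_ly, res$inc_cost / res$inc_ly)
  expect_false(res$cost_effective)

  # identical strategies: zero incrementals, no ICER, no dominance
  same <- compute_icer(tot$chemo, tot$chemo)
  expect_equal(same$inc_cost, 0)
  expect_equal(same$inc_qaly, 0)
  expect_true(is.na(same$icer_per_qaly))
  expect_equal(same$dominance, "none")

  # equal effects, higher cost: undefined ICER, dominance by cost
  a <- strategy_totals("a", 1000, 2, 1.5)
  b <- strategy_totals("b", 800, 2, 1.5)
  r <- compute_icer(a, b)
  expect_true(is.na(r$icer_per_qaly))
  expect_equal(r$dominance, "dominated")
  # cheaper and more effective: dominant and cost-effective
  r2 <- compute_icer(strategy_totals("c", 500, 2.5, 2), a)
  expect_equal(r2$dominance, "dominant")
  expect_true(r2$cost_effective)
})

test_that("net monetary benefit identities", {
  tot <- strategy_totals("x", 5000, 2, 1.5)
  expect_equal(net_monetary_benefit(tot, 0), -5000)
  expect_equal(net_monetary_benefit(tot, 20000), 20000 * 1.5 - 5000)
  res <- compute_icer(printed_totals()$pembro, printed_totals()$chemo)
  # paper-scale arithmetic: 38223.34 * 0.09 - 36976.41
  expect_equal(net_monetary_benefit(res, 38223.34),
               38223.34 * 0.09 - 36976.41)
  expect_error(net_monetary_benefit(tot, -1), "non-negative")
  # positive incremental NMB <=> ICER below WTP when dQALY > 0
  set.seed(71)
  for (i in 1:20) {
    r <- compute_icer(strategy_totals("a", runif(1, 0, 5e4), 2,
                                      runif(1, 1, 3)),
                      strategy_totals("b", runif(1, 0, 5e4), 2,
                                      runif(1, 0.5, 1)))
    w <- runif(1, 0, 1e5)
    expect_equal(net_monetary_benefit(r, w) > 0, r$icer_per_qaly < w)
  }
})

test_that("totals respond monotonically to unit costs and utilities", {
  model <- quiet_build_model()
  base <- evaluate_model(model)
  up_cost <- evaluate_model(model, list(cost_pembrolizumab_cycle = 6000))
  st <- function(r, s) r$strategies[r$strategies$name == s, ]
  expect_gt(st(up_cost, "pembrolizumab")$cost,
            st(base, "pembrolizumab")$cost)
  expect_equal(st(up_cost, "chemotherapy")$cost,
               st(base, "chemotherapy")$cost)
  up_u <- evaluate_model(model, list(u_pfs = 0.91))
  expect_gt(st(up_u, "pembrolizumab")$qaly, st(base, "pembrolizumab")$qaly)
  # QALY never exceeds LY (utilities <= 1)
  for (r in list(base, up_cost, up_u)) {
    expect_true(all(r$strategies$qaly <= r$strategies$ly + 1e-12))
  }
})
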