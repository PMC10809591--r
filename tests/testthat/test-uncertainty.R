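test_that("moment-matched gamma reproduces its mean and SD", {
  spec <- param_spec("cost_anemia", 6562.68, 5250.14, 7875.22, "gamma")
  s <- moment_matched_distribution(spec)
  expect_equal(s$mean, 6562.68)
  expect_equal(s$sd, (7875.22 - 5250.14) / 3.92)
  set.seed(101)
  draws <- s$sample(10000)
  expect_lt(abs(mean(draws) - s$mean) / s$mean, 0.02)
  expect_lt(abs(sd(draws) - s$sd) / s$sd, 0.02)
  expect_true(all(draws > 0))
})

test_that("moment-matched beta stays in (0,1) with the right moments", {
  spec <- param_spec("u_pfs", 0.76, 0.61, 0.91, "beta")
  s <- moment_matched_distribution(spec)
  set.seed(102)
  draws <- s$sample(10000)
  expect_true(all(draws > 0 & draws < 1))
  expect_lt(abs(mean(draws) - 0.76) / 0.76, 0.02)
  expect_lt(abs(sd(draws) - s$sd) / s$sd, 0.02)
})

test_that("degenerate and infeasible specs are handled explicitly", {
  # zero width: point mass regardless of distribution
  pm <- moment_matched_distribution(param_spec("x", 5, 5, 5, "gamma"))
  expect_equal(pm$sample(50), rep(5, 50))
  z <- moment_matched_distribution(
    param_spec("p_zero", 0, 0, 0, "beta"))
  expect_equal(z$sample(10), rep(0, 10))
  # beta needs a base strictly inside (0,1) when it has spread
  expect_error(moment_matched_distribution(
    param_spec("p_edge", 0, 0, 0.2, "beta")), "\\(0, 1\\)")
  # moments infeasible for a beta: SD^2 >= mean(1-mean)
  expect_error(moment_matched_distribution(
    param_spec("p_wide", 0.05, 0, 0.9, "beta")), "infeasible")
  expect_error(param_spec("bad", 1, 2, 0.5), "low <= base <= high")
  expect_error(param_spec("bad_beta", 0.5, 0.1, 1.2, "beta"),
               "within \\[0, 1\\]")
})

test_that("the default parameter table covers the model registry", {
  specs <- default_param_specs()
  expect_true(all(specs$low <= specs$base & specs$base <= specs$high))
  expect_true(all(specs$distribution[grepl("^cost_", specs$name)] ==
                    "gamma"))
  expect_true(all(specs$distribution[grepl("^(u_|p_)", specs$name)] ==
                    "beta"))
  # discount excluded from PSA by default, re-enabled on request
  expect_equal(specs$distribution[specs$name == "discount_rate"], "fixed")
  s2 <- default_param_specs(include_discount = TRUE)
  expect_equal(s2$distribution[s2$name == "discount_rate"], "beta")
  # AE incidences use +/-20% of base
  an <- specs[specs$name == "p_anemia_chemotherapy", ]
  expect_equal(c(an$low, an$high), c(0.8, 1.2) * 0.107)
})

test_that("tornado spans equal brute-force model re-evaluation", {
  model <- quiet_build_model()
  specs <- default_param_specs()
  tor <- one_way_dsa(model, specs)
  expect_setequal(tor$parameter, specs$name)
  expect_true(all(tor$span >= 0))
  expect_true(all(diff(tor$span) <= 1e-9))  # sorted descending

  # oracle: rebuild the whole model from a modified config (slow path,
  # independent of the override fast path) and compare ICERs at bounds
  brute <- function(name, value) {
    cfg <- default_config()
    if (name == "cost_pembrolizumab_cycle") {
      cfg$costs$pembrolizumab_cycle <- value
    } else if (name == "u_pfs") {
      cfg$utilities$u_pfs <- value
    } else if (name == "discount_rate") {
      cfg$plan$annual_discount <- value
    }
    evaluate_model(quiet_build_model(cfg))$icer_per_qaly
  }
  for (nm in c("cost_pembrolizumab_cycle", "u_pfs", "discount_rate")) {
    row <- tor[tor$parameter == nm, ]
    expect_equal(row$icer_low, brute(nm, row$low), tolerance = 1e-8)
    expect_equal(row$icer_high, brute(nm, row$high), tolerance = 1e-8)
    expect_equal(row$span, abs(row$icer_high - row$icer_low))
  }

  # a degenerate parameter has zero span; unknown names are rejected
  degen <- param_spec("u_pd", 0.35, 0.35, 0.35, "beta")
  expect_equal(one_way_dsa(model, degen)$span, 0)
  expect_error(one_way_dsa(model, param_spec("not_a_param", 1, 0, 2,
                                             "gamma")), "unknown")
})

test_that("PSA is reproducible and centred on the base case", {
  model <- quiet_build_model()
  specs <- default_param_specs()
  p1 <- run_psa(model, specs, n_iter = 200, seed = 7)
  p2 <- run_psa(model, specs, n_iter = 200, seed = 7)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), 200)
  expect_false(anyNA(p1))

  base <- evaluate_model(model)
  expect_lt(abs(mean(p1$inc_cost) - base$inc_cost) /
              abs(base$inc_cost), 0.05)

  # all parameters fixed: every iteration equals the base case
  fixed <- specs
  fixed$distribution <- "fixed"
  pf <- run_psa(model, fixed, n_iter = 5, seed = 1)
  expect_equal(pf$inc_cost, rep(base$inc_cost, 5))
  expect_equal(pf$inc_qaly, rep(base$inc_qaly, 5))
})

test_that("CEAC probabilities match an independent per-draw count", {
  model <- quiet_build_model()
  psa <- run_psa(model, n_iter = 200, seed = 12)
  grid <- c(0, 38223.34, 1e5, 1e7)
  cc <- ceac(psa, grid)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # independent route: compare per-strategy net benefits draw by draw
  for (i in seq_along(grid)) {
    w <- grid[i]
    wins <- sum((w * psa$qaly_ref - psa$cost_ref) >
                  (w * psa$qaly_comp - psa$cost_comp))
    expect_equal(cc$probability[i], wins / nrow(psa))
  }
  # at WTP 0 this is just "reference is cheaper" — never true here
  expect_equal(cc$probability[1], mean(psa$inc_cost < 0))
  expect_error(ceac(psa, numeric(0)), "non-empty")

  # a strategy dominant in every draw is accepted at any threshold
  dom <- psa
  dom$inc_cost <- -abs(dom$inc_cost)
  dom$inc_qaly <- abs(dom$inc_qaly) + 0.01
  expect_true(all(ceac(dom, grid)$probability == 1))
})

test_that("the CE plane has one point per iteration", {
  model <- quiet_build_model()
  psa <- run_psa(model, n_iter = 150, seed = 13)
  pl <- ce_plane(psa)
  expect_equal(nrow(pl), 150)
  quad <- table(factor(paste0(pl$inc_qaly >= 0, pl$inc_cost >= 0),
                       levels = c("TRUETRUE", "TRUEFALSE", "FALSETRUE",
                                  "FALSEFALSE")))
  expect_equal(sum(quad), 150L)
  # the calibrated model's incremental cost is dominated by the drug
  # price: essentially every draw lies in the upper half-plane
  expect_gte(mean(pl$inc_cost > 0), 0.99)
})
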