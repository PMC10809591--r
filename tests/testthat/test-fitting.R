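test_that("exponential MLE equals its closed form", {
  # uncensored: lambda-hat = n / sum(t); censored: events / sum(all times)
  d <- simulate_arm_ipd("exponential", c(rate = 1 / 300), n = 400,
                        seed = 14)
  fit <- fit_parametric(d, "exponential")
  expect_true(fit$converged)
  expect_equal(fit$curve$params[["rate"]],
               sum(d$event) / sum(d$time_days), tolerance = 1e-4)

  dc <- simulate_arm_ipd("exponential", c(rate = 1 / 300), n = 400,
                         censor = list(accrual_days = 200,
                                       cutoff_days = 800), seed = 15)
  fitc <- fit_parametric(dc, "exponential")
  expect_equal(fitc$curve$params[["rate"]],
               sum(dc$event) / sum(dc$time_days), tolerance = 1e-4)
})

test_that("uncensored lognormal MLE equals log-moment estimates", {
  d <- simulate_arm_ipd("lognormal", c(meanlog = 5.2, sdlog = 0.9),
                        n = 500, seed = 16)
  fit <- fit_parametric(d, "lognormal")
  lt <- log(d$time_days)
  mu_hat <- mean(lt)
  sd_hat <- sqrt(mean((lt - mu_hat)^2))  # 1/n MLE variant
  expect_equal(fit$curve$params[["meanlog"]], mu_hat, tolerance = 1e-4)
  expect_equal(fit$curve$params[["sdlog"]], sd_hat, tolerance = 1e-3)
})

test_that("Weibull shape is recovered from simulated data", {
  d <- simulate_arm_ipd("weibull", c(shape = 1.4, scale = 400), n = 1000,
                        seed = 17)
  fit <- fit_parametric(d, "weibull")
  expect_lt(abs(fit$curve$params[["shape"]] - 1.4) / 1.4, 0.10)
})

test_that("AIC and BIC identities hold with n = subjects", {
  d <- simulate_arm_ipd("exponential", c(rate = 1 / 200), n = 120,
                        seed = 18)
  for (fam in c("exponential", "weibull", "generalized_gamma")) {
    fit <- fit_parametric(d, fam)
    expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
    expect_equal(fit$bic, fit$k * log(120) - 2 * fit$loglik)
    expect_equal(fit$n, 120L)
  }
  expect_equal(fit_parametric(d, "exponential")$k, 1L)
  expect_equal(fit_parametric(d, "gompertz")$k, 2L)
  expect_equal(fit_parametric(d, "generalized_gamma")$k, 3L)
})

test_that("fitting demands at least one event", {
  d <- ipd_dataset(c(10, 20), c(0, 0), "a")
  expect_error(fit_parametric(d, "exponential"), "no events")
})

test_that("model selection returns the minimum-criterion converged fit", {
  mk <- function(family, aic, bic, k, converged = TRUE) {
    structure(list(curve = NULL, loglik = 0, k = k, n = 100, aic = aic,
                   bic = bic, converged = converged, family = family),
              class = "fit_result")
  }
  fits <- list(mk("weibull", 105, 110, 2L), mk("exponential", 100, 102, 1L),
               mk("gompertz", 101, 106, 2L))
  expect_equal(select_model(fits, "AIC")$family, "exponential")
  # tie on the criterion: fewer parameters wins, then family name
  tie <- list(mk("weibull", 100, 105, 2L), mk("exponential", 100, 102, 1L))
  expect_equal(select_model(tie, "AIC")$family, "exponential")
  tie2 <- list(mk("weibull", 100, 105, 2L), mk("loglogistic", 100, 105, 2L))
  expect_equal(select_model(tie2, "AIC")$family, "loglogistic")
  # single candidate returned unchanged; non-converged excluded
  single <- mk("lognormal", 99, 101, 2L)
  expect_equal(select_model(list(single))$family, "lognormal")
  bad <- list(mk("weibull", 1, 1, 2L, converged = FALSE))
  expect_error(select_model(bad), "no converged")
  mixed <- list(mk("weibull", 1, 1, 2L, converged = FALSE),
                mk("lognormal", 500, 500, 2L))
  expect_equal(select_model(mixed)$family, "lognormal")
})

test_that("selection recovers the generating family on large samples", {
  # lognormal-generated PFS-like data
  d_ln <- simulate_arm_ipd("lognormal",
                           c(meanlog = log(months_to_days(4.1)),
                             sdlog = 1), n = 1000, seed = 42)
  best_ln <- select_model(fit_all_families(d_ln), "AIC")
  expect_equal(best_ln$family, "lognormal")
  tab <- attr(best_ln, "criterion_table")
  expect_setequal(tab$family, supported_families())
  expect_true(all(is.finite(tab$aic[tab$converged])))

  # exponential-generated OS-like data (BIC penalises the nesting
  # families more strongly, making single-replicate selection stable)
  d_ex <- simulate_arm_ipd("exponential",
                           c(rate = log(2) / months_to_days(17.2)),
                           n = 1000, seed = 42)
  expect_equal(select_model(fit_all_families(d_ex), "BIC")$family,
               "exponential")
})

test_that("criterion tables export with the documented columns", {
  d <- simulate_arm_ipd("exponential", c(rate = 1 / 250), n = 150,
                        seed = 19)
  fits <- fit_all_families(d, c("exponential", "weibull"))
  tab <- criterion_table(fits)
  expect_named(tab, c("family", "loglik", "k", "aic", "bic", "converged"))
  f <- tempfile(fileext = ".csv")
  write_criterion_csv(fits, f)
  expect_equal(nrow(utils::read.csv(f)), 2)
  unlink(f)
})

test_that("pseudo-IPD reconstruction round-trips a digitized curve", {
  set.seed(23)
  d <- simulate_arm_ipd("exponential", c(rate = 1 / 500), n = 250,
                        censor = list(accrual_days = 300,
                                      cutoff_days = 1200), seed = 11)
  km <- km_estimate(d, risk_times = seq(0, 1200, by = 150))

  # with the numbers-at-risk table
  rec <- reconstruct_ipd_from_km(km)
  expect_lt(km_sup_norm(km_estimate(rec), km), 0.02)

  # without it (censoring assumed only at curve end)
  plain <- km_digitized(km$time_days, km$survival)
  rec2 <- reconstruct_ipd_from_km(plain, n_start = 200)
  expect_lt(km_sup_norm(km_estimate(rec2), km), 0.02)
})

test_that("reconstruction plus refit recovers a known exponential", {
  lam <- 1 / 400
  grid <- seq(0, 1600, by = 40)
  km <- km_digitized(grid, exp(-lam * grid))
  rec <- reconstruct_ipd_from_km(km, n_start = 500)
  fit <- fit_parametric(rec, "exponential")
  expect_lt(abs(fit$curve$params[["rate"]] - lam) / lam, 0.10)
})

test_that("degenerate digitized curves are rejected", {
  flat <- km_digitized(c(0, 100, 200), c(1, 1, 1))
  expect_error(reconstruct_ipd_from_km(flat), "no events")
  expect_error(km_digitized(c(0, 50, 100), c(1, 0.4, 0.9)),
               "non-increasing")
})
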