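# shared fixtures and small utilities for the test suite

# the packaged base case builds with a (documented) PFS/OS clamp warning in
# the first cycle; tests that are not about the clamp silence it
quiet_build_model <- function(config = default_config()) {
  suppressWarnings(build_model(config))
}

# sup-norm distance between two right-continuous step functions, evaluated
# on the union of their jump points
km_sup_norm <- function(km_a, km_b) {
  fa <- stats::approxfun(km_a$time_days, km_a$survival,
                         method = "constant", rule = 2)
  fb <- stats::approxfun(km_b$time_days, km_b$survival,
                         method = "constant", rule = 2)
  grid <- sort(unique(c(km_a$time_days, km_b$time_days)))
  max(abs(fa(grid) - fb(grid)))
}

# hand-built cohort trace for accrual arithmetic tests
make_trace <- function(pfs, pd, dead, discount = 1) {
  n <- length(pfs)
  structure(data.frame(cycle = seq_len(n), t_days = (seq_len(n) - 0.5) * 21,
                       pfs = pfs, pd = pd, dead = dead,
                       new_deaths = pmax(0, diff(c(0, dead))),
                       on_treatment = pfs,
                       discount_factor = rep_len(discount, n)),
            class = c("psm_trace", "data.frame"))
}

# random monotone survival-curve pair (PFS shorter than OS on average)
random_curve_pair <- function() {
  fam <- sample(c("exponential", "weibull", "lognormal"), 2, replace = TRUE)
  mk <- function(f, med) {
    switch(f,
      exponential = parametric_curve("exponential",
                                     c(rate = log(2) / med)),
      weibull = parametric_curve("weibull",
                                 c(shape = runif(1, 0.8, 2),
                                   scale = med * runif(1, 0.9, 1.4))),
      lognormal = parametric_curve("lognormal",
                                   c(meanlog = log(med),
                                     sdlog = runif(1, 0.5, 1.5))))
  }
  os_med <- runif(1, 200, 700)
  pfs_med <- runif(1, 50, 250)
  list(os = mk(fam[1], os_med), pfs = mk(fam[2], pfs_med))
}

# table-printed base results (two-strategy totals) used for arithmetic
# consistency checks
printed_totals <- function() {
  list(chemo = strategy_totals("chemotherapy", 2734.55, 3.93, 2.73),
       pembro = strategy_totals("pembrolizumab", 39710.96, 3.96, 2.82))
}
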