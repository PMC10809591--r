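#' Build the cycle grid for the cohort model
#'
#' The model advances in fixed treatment cycles (default 21 days) over a
#' fixed horizon (default 5 years). The number of cycles is
#' `ceiling(horizon * 365.25 / cycle_length)` — 87 for the defaults — so the
#' stated horizon is never truncated. Under the midpoint convention
#' (half-cycle correction), state memberships and discount factors are
#' evaluated at `t_k = (k - 0.5) * cycle_length`.
#'
#' @param horizon_years Model horizon in years (> 0). Default 5.
#' @param cycle_length_days Cycle length in days (> 0). Default 21.
#' @param annual_discount Annual discount rate (>= 0). Default 0.05.
#' @param evaluation `"midpoint"` (half-cycle correction, default) or
#'   `"boundary"` (end-of-cycle evaluation).
#' @return A list of class `cycle_plan` with the evaluation-time grid and
#'   per-cycle discount factors.
#' @examples
#' plan <- build_cycle_plan()
#' plan$n_cycles  # 87
#' @export
build_cycle_plan <- function(horizon_years = 5, cycle_length_days = 21,
                             annual_discount = 0.05,
                             evaluation = c("midpoint", "boundary")) {
  evaluation <- match.arg(evaluation)
  if (horizon_years <= 0 || cycle_length_days <= 0) {
    stop("horizon and cycle length must be strictly positive")
  }
  if (annual_discount < 0) stop("discount rate must be non-negative")
  # small tolerance so an exact integer number of cycles is not pushed up
  # by floating-point noise
  n_cycles <- as.integer(ceiling(horizon_years * DAYS_PER_YEAR /
                                   cycle_length_days - 1e-9))
  k <- seq_len(n_cycles)
  eval_times <- if (evaluation == "midpoint") {
    (k - 0.5) * cycle_length_days
  } else {
    k * cycle_length_days
  }
  structure(list(horizon_years = horizon_years,
                 cycle_length_days = cycle_length_days,
                 annual_discount = annual_discount,
                 evaluation = evaluation,
                 n_cycles = n_cycles,
                 eval_times = eval_times,
                 discount_factors = discount_factor(eval_times,
                                                    annual_discount)),
            class = "cycle_plan")
}

#' @export
print.cycle_plan <- function(x, ...) {
  cat(sprintf(
    "<cycle_plan> %d cycles of %g days over %g years; discount %g (%s)\n",
    x$n_cycles, x$cycle_length_days, x$horizon_years, x$annual_discount,
    x$evaluation))
  invisible(x)
}

#' Read a life table from CSV
#'
#' Expected columns: `age` (years, strictly increasing) and `qx` (annual
#' probability of death, in `[0, 1]`).
#'
#' @param path CSV file path.
#' @return A data frame of class `life_table`.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  life_table(d$age, d$qx)
}

#' @rdname read_life_table
#' @param age Ages in years (strictly increasing).
#' @param qx Annual death probabilities.
#' @export
life_table <- function(age, qx) {
  if (any(qx < 0) || any(qx > 1)) stop("qx must lie in [0, 1]")
  if (is.unsorted(age, strictly = TRUE)) {
    stop("ages must be strictly increasing")
  }
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Synthetic general-population life table
#'
#' Loads the packaged synthetic life table (Gompertz-Makeham shaped annual
#' death probabilities, ages 0-100). It is a constructed stand-in for a
#' national life table, shipped so background-mortality blending is
#' runnable and testable without external data; it is not real national
#' mortality data.
#'
#' @return A [life_table()].
#' @export
synthetic_life_table <- function() {
  path <- system.file("extdata", "life_table_synthetic.csv",
                      package = "psmcea", mustWork = TRUE)
  read_life_table(path)
}

# daily background hazard at attained age (years); ages beyond the table
# use the last row
background_hazard_daily <- function(lt, age_years) {
  if (any(age_years > max(lt$age))) {
    warning("age exceeds life table range; using last-row qx")
  }
  idx <- pmin(findInterval(age_years, lt$age), nrow(lt))
  idx[idx < 1] <- 1
  q <- lt$qx[idx]
  -log(pmax(1 - q, 1e-12)) / DAYS_PER_YEAR
}

#' Blend a model OS curve with background mortality
#'
#' Applies general-population mortality as a hazard floor on the modelled
#' overall-survival hazard: `h*(t) = max(h_model(t), h_background(age + t))`
#' and `S*(t) = exp(-integral of h*)`, evaluated on a daily grid. The
#' adjusted curve never exceeds the model curve.
#'
#' @param os_curve A [parametric_curve()] (or plain survival function) for
#'   modelled OS.
#' @param life_table A [life_table()].
#' @param start_age Cohort age at model start (years). Default 50.
#' @param horizon_days Grid extent in days (default 10 years).
#' @return An object of class `adjusted_survival`; evaluate it with
#'   [survival_at()].
#' @export
apply_background_mortality <- function(os_curve, life_table, start_age = 50,
                                       horizon_days = 10 * DAYS_PER_YEAR) {
  stopifnot(inherits(life_table, "life_table"))
  if (start_age < min(life_table$age)) {
    stop("start_age below life-table range")
  }
  grid <- seq(0, ceiling(horizon_days), by = 1)
  s_model <- survival_at(os_curve, grid)
  # model hazard increments from -log S differences (exact for the grid)
  logs <- log(pmax(s_model, 1e-300))
  dH_model <- pmax(0, -diff(logs))
  ages <- start_age + (grid[-length(grid)] + 0.5) / DAYS_PER_YEAR
  dH_bg <- background_hazard_daily(life_table, ages)  # per day * 1-day step
  dH <- pmax(dH_model, dH_bg)
  s_adj <- exp(-cumsum(c(0, dH)))
  fn <- approxfun(grid, log(pmax(s_adj, 1e-300)), rule = 2)
  structure(list(surv = function(t) pmin(1, pmax(0, exp(fn(t)))),
                 start_age = start_age),
            class = "adjusted_survival")
}

#' Partition cohort membership from OS and PFS curves
#'
#' Core partitioned-survival step: at each evaluation time `t_k`,
#' `pfs = min(S_pfs(t_k), S_os(t_k))`, `dead = 1 - S_os(t_k)` and
#' `pd` is the remainder, so the three memberships always sum to 1.
#' Independently fitted curves can cross (PFS above OS); the crossing is
#' clamped and reported with a warning.
#'
#' @param os,pfs OS and PFS curves: [parametric_curve()],
#'   `adjusted_survival`, or plain functions of time in days.
#' @param plan A [build_cycle_plan()].
#' @return A data frame of class `psm_trace` with columns `cycle`, `t_days`,
#'   `pfs`, `pd`, `dead`, `new_deaths`, `on_treatment` (initialised to
#'   `pfs`; see [on_treatment_occupancy()]) and `discount_factor`.
#' @examples
#' os <- curve_from_median("exponential", 15.3)
#' pf <- curve_from_median("lognormal", 5.5, sigma = 1)
#' tr <- partition_memberships(os, pf, build_cycle_plan())
#' @export
partition_memberships <- function(os, pfs, plan) {
  stopifnot(inherits(plan, "cycle_plan"))
  tk <- plan$eval_times
  s_os <- survival_at(os, tk)
  s_pfs <- survival_at(pfs, tk)
  crossed <- s_pfs > s_os + 1e-12
  if (any(crossed)) {
    rng <- range(tk[crossed])
    warning(sprintf(
      "PFS curve exceeds OS curve between day %.1f and day %.1f; clamped",
      rng[1], rng[2]))
  }
  m_pfs <- pmin(s_pfs, s_os)
  m_dead <- 1 - s_os
  m_pd <- pmax(0, 1 - m_pfs - m_dead)
  new_deaths <- diff(c(0, m_dead))
  new_deaths[new_deaths < 0] <- 0
  structure(data.frame(cycle = seq_len(plan$n_cycles),
                       t_days = tk,
                       pfs = m_pfs, pd = m_pd, dead = m_dead,
                       new_deaths = new_deaths,
                       on_treatment = m_pfs,
                       discount_factor = plan$discount_factors),
            class = c("psm_trace", "data.frame"))
}

#' Apply a treatment-duration cap to a trace
#'
#' Drug is given while progression-free, up to an optional maximum number of
#' cycles: `on_treatment_k = pfs_k` for `k <= cap`, 0 after.
#'
#' @param trace A `psm_trace`.
#' @param cap_cycles Maximum treated cycles, or `NULL` for
#'   treat-to-progression.
#' @return The trace with its `on_treatment` column updated.
#' @export
on_treatment_occupancy <- function(trace, cap_cycles = NULL) {
  stopifnot(inherits(trace, "psm_trace"))
  if (is.null(cap_cycles)) {
    trace$on_treatment <- trace$pfs
    return(trace)
  }
  if (cap_cycles < 0) stop("treatment cap must be non-negative")
  trace$on_treatment <- ifelse(trace$cycle <= cap_cycles, trace$pfs, 0)
  trace
}

#' Export a model trace as CSV
#'
#' @param trace A `psm_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "psm_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
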