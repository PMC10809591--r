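#' Parameter specification for sensitivity analysis
#'
#' @param name Model parameter name (must be one the model recognises; see
#'   [default_param_specs()]).
#' @param base Base-case value.
#' @param low,high Range bounds (`low <= base <= high`). Printed 95%
#'   intervals are used directly; parameters without a published range use
#'   +/-20% of base.
#' @param distribution `"gamma"` (costs), `"beta"` (utilities and
#'   incidences, requires values in `[0, 1]`) or `"fixed"`.
#' @return A one-row data frame of class `param_spec`.
#' @export
param_spec <- function(name, base, low, high,
                       distribution = c("gamma", "beta", "fixed")) {
  distribution <- match.arg(distribution)
  if (!(low <= base && base <= high)) {
    stop(sprintf("'%s': need low <= base <= high", name))
  }
  if (distribution == "beta" && (low < 0 || high > 1)) {
    stop(sprintf("'%s': beta distribution needs a range within [0, 1]",
                 name))
  }
  structure(data.frame(name = name, base = base, low = low, high = high,
                       distribution = distribution,
                       stringsAsFactors = FALSE),
            class = c("param_spec", "data.frame"))
}

#' Default sensitivity-analysis parameter table
#'
#' The base-case values and ranges of the shipped model: drug, adverse
#' event, monitoring and terminal-care costs with their published 95%
#' ranges (gamma); utilities and adverse-event incidences (beta; the
#' incidences have no published range and use +/-20% of base). The discount
#' rate (range 0-8%) takes part in one-way sensitivity analysis and
#' scenarios but is treated as structural — `"fixed"` — in probabilistic
#' analysis unless `include_discount = TRUE`.
#'
#' @param config A [default_config()]-shaped list (for base values).
#' @param include_discount Sample the discount rate in PSA (beta on 0-0.08).
#' @return A data frame of `param_spec` rows.
#' @export
default_param_specs <- function(config = default_config(),
                                include_discount = FALSE) {
  p20 <- function(x) c(low = 0.8 * x, high = 1.2 * x)
  ae <- config$ae_probabilities
  rows <- list(
    param_spec("cost_pembrolizumab_cycle", config$costs$pembrolizumab_cycle,
               4262.32, 5327.90, "gamma"),
    param_spec("cost_capecitabine_cycle", config$costs$capecitabine_cycle,
               29.11, 36.39, "gamma"),
    param_spec("cost_gemcitabine_cycle", config$costs$gemcitabine_cycle,
               35.33, 44.16, "gamma"),
    param_spec("cost_docetaxel_cycle", config$costs$docetaxel_cycle,
               24.98, 31.22, "gamma"),
    param_spec("cost_anemia", config$costs$anemia,
               5250.14, 7875.22, "gamma"),
    param_spec("cost_neutrocytopenia", config$costs$neutrocytopenia,
               380.26, 570.38, "gamma"),
    param_spec("cost_imaging", config$costs$imaging,
               165.80, 248.70, "gamma"),
    param_spec("cost_lab", config$costs$lab, 9.51, 14.27, "gamma"),
    param_spec("cost_terminal_care", config$costs$terminal_care,
               109.23, 1825.38, "gamma"),
    param_spec("u_pfs", config$utilities$u_pfs, 0.61, 0.91, "beta"),
    param_spec("u_pd", config$utilities$u_pd, 0.28, 0.42, "beta"))
  for (s in names(ae)) {
    for (e in names(ae[[s]])) {
      b <- unname(ae[[s]][e])
      r <- p20(b)
      rows <- c(rows, list(param_spec(
        paste0("p_", e, "_", s), b, unname(r["low"]),
        min(1, unname(r["high"])), "beta")))
    }
  }
  rows <- c(rows, list(param_spec(
    "discount_rate", config$plan$annual_discount, 0, 0.08,
    if (include_discount) "beta" else "fixed")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Moment-matched sampler for a parameter
#'
#' Interprets the printed range as a 95% interval, `SD = (high - low)/3.92`,
#' and matches mean = base: gamma with `shape = mean^2/SD^2`,
#' `scale = SD^2/mean`; beta with
#' `alpha = mean * (mean(1-mean)/SD^2 - 1)`, `beta = alpha (1-mean)/mean`.
#' `SD = 0` (or `"fixed"`) gives a point mass at base.
#'
#' @param spec A one-row [param_spec()].
#' @return A list with `sample(n)` (draws using the session RNG), `mean`,
#'   `sd`, `distribution` and the matched shape parameters.
#' @export
moment_matched_distribution <- function(spec) {
  stopifnot(nrow(spec) == 1)
  base <- spec$base; sd <- (spec$high - spec$low) / 3.92
  dist <- spec$distribution
  if (dist == "fixed" || sd == 0) {
    return(list(sample = function(n) rep(base, n), mean = base, sd = 0,
                distribution = "point", params = NULL))
  }
  if (dist == "gamma") {
    if (base <= 0) stop(sprintf("'%s': gamma needs base > 0", spec$name))
    shape <- base^2 / sd^2
    scale <- sd^2 / base
    return(list(sample = function(n) stats::rgamma(n, shape = shape,
                                                   scale = scale),
                mean = base, sd = sd, distribution = "gamma",
                params = c(shape = shape, scale = scale)))
  }
  if (dist == "beta") {
    if (base <= 0 || base >= 1) {
      stop(sprintf("'%s': beta needs base in (0, 1)", spec$name))
    }
    nu <- base * (1 - base) / sd^2 - 1
    if (nu <= 0) {
      stop(sprintf("'%s': infeasible beta moments (mean %.4g, sd %.4g)",
                   spec$name, base, sd))
    }
    alpha <- base * nu
    beta <- alpha * (1 - base) / base
    return(list(sample = function(n) stats::rbeta(n, alpha, beta),
                mean = base, sd = sd, distribution = "beta",
                params = c(alpha = alpha, beta = beta)))
  }
  stop("unknown distribution: ", dist)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the full model with each parameter at its low and high
#' bound, all others at base. Rows are sorted by descending ICER
#' (per QALY) span; rows whose ICER range straddles the willingness-to-pay
#' threshold are flagged. Incremental net-monetary-benefit columns are
#' included since ICERs are unstable when the incremental QALY is near
#' zero.
#'
#' @param model A [build_model()] result.
#' @param specs A [default_param_specs()]-shaped data frame.
#' @param wtp Willingness-to-pay (USD/QALY); defaults to the model's.
#' @return Data frame of class `tornado_table`: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, `crosses_wtp`, `inmb_low`,
#'   `inmb_high`.
#' @export
one_way_dsa <- function(model, specs = default_param_specs(model$config),
                        wtp = NULL) {
  stopifnot(inherits(model, "psm_model"))
  wtp <- wtp %||% model$config$wtp
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    res_lo <- evaluate_model(model, setNames(list(sp$low), sp$name))
    res_hi <- evaluate_model(model, setNames(list(sp$high), sp$name))
    icer_lo <- res_lo$icer_per_qaly
    icer_hi <- res_hi$icer_per_qaly
    data.frame(parameter = sp$name, low = sp$low, high = sp$high,
               icer_low = icer_lo, icer_high = icer_hi,
               span = abs(icer_hi - icer_lo),
               crosses_wtp = (min(icer_lo, icer_hi) <= wtp &&
                              max(icer_lo, icer_hi) >= wtp),
               inmb_low = net_monetary_benefit(res_lo, wtp),
               inmb_high = net_monetary_benefit(res_hi, wtp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado_table", "data.frame"))
}

#' Probabilistic sensitivity analysis
#'
#' Joint Monte Carlo sampling of all non-fixed parameters from their
#' moment-matched distributions (independently across parameters), with the
#' model evaluated at each draw. Survival curves are structural and stay
#' fixed. Reproducible under a fixed seed.
#'
#' @param model A [build_model()] result.
#' @param specs Parameter table ([default_param_specs()]).
#' @param n_iter Number of iterations (default 1000).
#' @param seed Integer seed.
#' @return A data frame of class `psa_results` with one row per iteration:
#'   per-strategy cost and QALY, `inc_cost`, `inc_qaly`; attributes
#'   `n_iterations`, `seed`, `wtp`, `reference`, `comparator`.
#' @export
run_psa <- function(model, specs = default_param_specs(model$config),
                    n_iter = 1000, seed = 1L) {
  stopifnot(inherits(model, "psm_model"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  set.seed(as.integer(seed))
  samplers <- lapply(seq_len(nrow(specs)), function(i) {
    moment_matched_distribution(specs[i, ])
  })
  draws <- vapply(samplers, function(s) s$sample(n_iter), numeric(n_iter))
  if (n_iter == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- specs$name
  active <- specs$name[specs$distribution != "fixed"]
  ref <- model$config$reference; comp <- model$config$comparator
  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    ov <- as.list(draws[it, active])
    res <- tryCatch(evaluate_model(model, ov), error = function(e) {
      stop(sprintf("PSA iteration %d failed (%s); draw: %s", it,
                   conditionMessage(e),
                   paste(sprintf("%s=%.6g", active,
                                 unlist(ov)), collapse = ", ")),
           call. = FALSE)
    })
    st <- res$strategies
    out[[it]] <- data.frame(
      iteration = it,
      cost_ref = st$cost[st$name == ref],
      qaly_ref = st$qaly[st$name == ref],
      cost_comp = st$cost[st$name == comp],
      qaly_comp = st$qaly[st$name == comp],
      inc_cost = res$inc_cost, inc_qaly = res$inc_qaly)
  }
  res <- do.call(rbind, out)
  structure(res, n_iterations = n_iter, seed = as.integer(seed),
            wtp = model$config$wtp, reference = ref, comparator = comp,
            draws = draws,
            class = c("psa_results", "data.frame"))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which the reference strategy has positive incremental net monetary
#' benefit (`wtp * inc_QALY - inc_cost > 0`).
#'
#' @param results A [run_psa()] result.
#' @param wtp_grid Non-empty vector of WTP values (USD/QALY).
#' @return Data frame with columns `wtp` and `probability` (in `[0, 1]`).
#' @export
ceac <- function(results, wtp_grid) {
  stopifnot(inherits(results, "psa_results"))
  if (length(wtp_grid) == 0) stop("wtp grid must be non-empty")
  prob <- vapply(wtp_grid, function(w) {
    mean(w * results$inc_qaly - results$inc_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Cost-effectiveness plane points
#'
#' One `(incremental QALY, incremental cost)` point per PSA iteration.
#'
#' @param results A [run_psa()] result.
#' @return Data frame with columns `inc_qaly`, `inc_cost`.
#' @export
ce_plane <- function(results) {
  stopifnot(inherits(results, "psa_results"))
  data.frame(inc_qaly = results$inc_qaly, inc_cost = results$inc_cost)
}
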