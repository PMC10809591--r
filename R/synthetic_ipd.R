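#' Individual patient data container
#'
#' An `ipd_dataset` is a data frame with columns `time_days` (strictly
#' positive follow-up time), `event` (1 = event, 0 = censored) and `arm`
#' (strategy label), plus an `endpoint` attribute (`"OS"` or `"PFS"`).
#'
#' @param time_days Positive follow-up times in days.
#' @param event Event indicators (0/1).
#' @param arm Arm labels (recycled if scalar).
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A data frame of class `ipd_dataset`.
#' @export
ipd_dataset <- function(time_days, event, arm = "arm",
                        endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  if (length(time_days) == 0) stop("empty dataset")
  if (any(!is.finite(time_days)) || any(time_days <= 0)) {
    stop("all times must be strictly positive and finite")
  }
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  out <- data.frame(time_days = as.numeric(time_days),
                    event = as.integer(event),
                    arm = rep_len(as.character(arm), length(time_days)),
                    stringsAsFactors = FALSE)
  structure(out, endpoint = endpoint, class = c("ipd_dataset", "data.frame"))
}

ipd_endpoint <- function(data) attr(data, "endpoint") %||% "OS"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one arm of trial-like survival data
#'
#' Event times are drawn from a parametric family; administrative censoring
#' follows uniform accrual over a window with a fixed data cutoff (follow-up
#' for a subject entering at `e` is `cutoff - e`). No loss to follow-up is
#' modelled.
#'
#' @param family One of [supported_families()].
#' @param params Named parameter vector (day scale), as in
#'   [parametric_curve()].
#' @param n Number of subjects (>= 1).
#' @param censor `NULL` for no censoring, or a list with `accrual_days`
#'   (window width, >= 0) and `cutoff_days` (administrative cutoff, must
#'   exceed `accrual_days`).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param arm Arm label.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return An [ipd_dataset()].
#' @examples
#' d <- simulate_arm_ipd("exponential",
#'                       c(rate = log(2) / months_to_days(17.2)),
#'                       n = 200, seed = 1)
#' @export
simulate_arm_ipd <- function(family, params, n, censor = NULL, seed = NULL,
                             arm = "arm", endpoint = "OS") {
  curve <- parametric_curve(family, params)  # validates params
  if (n < 1) stop("n must be >= 1")
  if (!is.null(censor)) {
    accrual <- censor$accrual_days %||% 0
    cutoff <- censor$cutoff_days %||% Inf
    if (accrual < 0) stop("accrual window must be non-negative")
    if (cutoff <= 0) stop("cutoff must be strictly positive")
    if (is.finite(cutoff) && cutoff <= accrual) {
      stop("cutoff must exceed the accrual window (no positive follow-up)")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  tt <- random_times(curve, n)
  if (is.null(censor)) {
    return(ipd_dataset(tt, 1L, arm, endpoint))
  }
  entry <- runif(n, 0, accrual)
  fup <- cutoff - entry
  time <- pmin(tt, fup)
  event <- as.integer(tt <= fup)
  ipd_dataset(time, event, arm, endpoint)
}

#' Define a two-arm trial simulation scenario
#'
#' The default scenario emulates a pembrolizumab-versus-chemotherapy trial
#' in recurrent/metastatic nasopharyngeal carcinoma: OS approximately
#' exponential with medians 17.2 / 15.3 months and PFS approximately
#' lognormal with medians 4.1 / 5.5 months (sdlog `sigma`, default 1.0),
#' uniform accrual and administrative censoring. Latent OS and PFS times
#' share a Gaussian copula with correlation `rho`; simulated PFS is
#' truncated at OS (progression-free survival ends at progression *or*
#' death), so `rho` close to 1 preserves the marginal PFS median.
#'
#' @param n_per_arm Subjects per arm (>= 2). Default 100.
#' @param os_median_months Named or ordered pair of OS medians (months).
#' @param pfs_median_months Pair of PFS medians (months).
#' @param sigma Lognormal sdlog for PFS. Default 1.0.
#' @param arms Arm labels.
#' @param accrual_days Accrual window (days).
#' @param cutoff_days Administrative cutoff (days). Default 5 years.
#' @param rho Latent Gaussian-copula correlation between PFS and OS.
#' @param seed Integer seed.
#' @return A list of class `trial_scenario`.
#' @export
trial_scenario <- function(n_per_arm = 100,
                           os_median_months = c(pembrolizumab = 17.2,
                                                chemotherapy = 15.3),
                           pfs_median_months = c(pembrolizumab = 4.1,
                                                 chemotherapy = 5.5),
                           sigma = 1.0,
                           arms = names(os_median_months),
                           accrual_days = 365,
                           cutoff_days = 5 * DAYS_PER_YEAR,
                           rho = 0.95,
                           seed = 1L) {
  if (n_per_arm < 2) stop("n_per_arm must be >= 2")
  if (cutoff_days <= 0) stop("cutoff must be strictly positive")
  if (cutoff_days <= accrual_days) {
    stop("cutoff must exceed the accrual window")
  }
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (is.null(arms)) arms <- c("arm1", "arm2")
  structure(list(n_per_arm = n_per_arm, arms = arms,
                 os_median_months = unname(os_median_months),
                 pfs_median_months = unname(pfs_median_months),
                 sigma = sigma, accrual_days = accrual_days,
                 cutoff_days = cutoff_days, rho = rho,
                 seed = as.integer(seed)),
            class = "trial_scenario")
}

#' Simulate a two-arm trial (OS and PFS endpoints)
#'
#' @param scenario A [trial_scenario()].
#' @return A list with elements `os` and `pfs`, each an [ipd_dataset()]
#'   covering both arms; per subject, PFS time <= OS time.
#' @examples
#' tr <- simulate_trial(trial_scenario(n_per_arm = 50, seed = 7))
#' @export
simulate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  set.seed(scenario$seed)
  os_list <- list(); pfs_list <- list()
  for (i in seq_along(scenario$arms)) {
    arm <- scenario$arms[i]
    os_curve <- curve_from_median("exponential",
                                  scenario$os_median_months[i])
    pfs_curve <- if (scenario$sigma <= 0) {
      NULL  # degenerate sigma -> 0: all PFS latent times at the median
    } else {
      curve_from_median("lognormal", scenario$pfs_median_months[i],
                        sigma = scenario$sigma)
    }
    n <- scenario$n_per_arm
    # Gaussian copula draws
    z1 <- stats::rnorm(n)
    z2 <- scenario$rho * z1 + sqrt(1 - scenario$rho^2) * stats::rnorm(n)
    os_t <- quantile_surv(os_curve, pnorm(z1))
    pfs_latent <- if (is.null(pfs_curve)) {
      rep(months_to_days(scenario$pfs_median_months[i]), n)
    } else {
      quantile_surv(pfs_curve, pnorm(z2))
    }
    pfs_t <- pmin(pfs_latent, os_t)  # progression-or-death <= death
    entry <- runif(n, 0, scenario$accrual_days)
    fup <- scenario$cutoff_days - entry
    os_list[[arm]] <- data.frame(
      time_days = pmin(os_t, fup), event = as.integer(os_t <= fup),
      arm = arm, stringsAsFactors = FALSE)
    pfs_list[[arm]] <- data.frame(
      time_days = pmin(pfs_t, fup), event = as.integer(pfs_t <= fup),
      arm = arm, stringsAsFactors = FALSE)
  }
  bind <- function(lst, ep) {
    d <- do.call(rbind, c(lst, list(make.row.names = FALSE)))
    ipd_dataset(d$time_days, d$event, d$arm, ep)
  }
  list(os = bind(os_list, "OS"), pfs = bind(pfs_list, "PFS"))
}

#' Kaplan-Meier estimate in digitized-curve form
#'
#' Computes the product-limit estimator for a single-arm dataset and returns
#' it in the (time, survival) step format that the curve-fitting stage also
#' accepts for digitized published curves, with a numbers-at-risk table on a
#' requested time grid.
#'
#' @param data An [ipd_dataset()] containing a single arm (subset first for
#'   multi-arm data).
#' @param risk_times Optional time grid (days) for the at-risk table;
#'   defaults to 6 equally spaced times from 0 to the last follow-up.
#' @return A `km_digitized` data frame with columns `time_days` and
#'   `survival` (starting at `(0, 1)`), with the risk table in
#'   `attr(, "risk_table")`.
#' @export
km_estimate <- function(data, risk_times = NULL) {
  stopifnot(inherits(data, "ipd_dataset"))
  if (length(unique(data$arm)) > 1) {
    stop("km_estimate expects a single arm; subset the dataset first")
  }
  if (sum(data$event) < 1) stop("no events in dataset")
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                           data = data)
  tab <- data.frame(time_days = c(0, fit$time),
                    survival = c(1, fit$surv))
  if (is.null(risk_times)) {
    risk_times <- seq(0, max(data$time_days), length.out = 6)
  }
  sm <- summary(fit, times = risk_times, extend = TRUE)
  risk <- data.frame(time_days = sm$time, n_risk = sm$n.risk)
  km_digitized(tab$time_days, tab$survival, risk_table = risk)
}

#' Digitized Kaplan-Meier curve container
#'
#' @param time_days Strictly increasing times (days, >= 0).
#' @param survival Non-increasing survival fractions in `[0, 1]`.
#' @param risk_table Optional data frame with columns `time_days`, `n_risk`
#'   (non-increasing counts).
#' @return A data frame of class `km_digitized`.
#' @export
km_digitized <- function(time_days, survival, risk_table = NULL) {
  if (length(time_days) != length(survival) || length(time_days) == 0) {
    stop("time and survival must be equal-length, non-empty")
  }
  if (any(time_days < 0)) stop("times must be non-negative")
  if (is.unsorted(time_days, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(survival < 0) || any(survival > 1)) {
    stop("survival values must lie in [0, 1]")
  }
  if (any(diff(survival) > 1e-12)) {
    stop("survival must be non-increasing")
  }
  if (!is.null(risk_table)) {
    stopifnot(all(c("time_days", "n_risk") %in% names(risk_table)))
    if (any(diff(risk_table$n_risk) > 0)) {
      stop("risk-table counts must be non-increasing in time")
    }
  }
  structure(data.frame(time_days = time_days, survival = survival),
            risk_table = risk_table,
            class = c("km_digitized", "data.frame"))
}

#' Read and write survival inputs as CSV
#'
#' `write_ipd_csv`/`read_ipd_csv` use columns `time_days`, `event`, `arm`;
#' `write_km_csv`/`read_km_csv` use `time_days`, `survival` and optionally
#' `n_risk`. Times are written with 6 decimal places.
#'
#' @param data An [ipd_dataset()] or [km_digitized()] object.
#' @param path File path.
#' @param endpoint Endpoint tag used when reading IPD.
#' @return The read functions return the reconstructed object; the write
#'   functions return `path` invisibly.
#' @name ipd_io
NULL

#' @rdname ipd_io
#' @export
write_ipd_csv <- function(data, path) {
  stopifnot(inherits(data, "ipd_dataset"))
  out <- data.frame(time_days = sprintf("%.6f", data$time_days),
                    event = data$event, arm = data$arm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_ipd_csv <- function(path, endpoint = "OS") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ipd_dataset(d$time_days, d$event, d$arm, endpoint)
}

#' @rdname ipd_io
#' @export
write_km_csv <- function(data, path) {
  stopifnot(inherits(data, "km_digitized"))
  out <- data.frame(time_days = sprintf("%.6f", data$time_days),
                    survival = sprintf("%.6f", data$survival))
  rt <- attr(data, "risk_table")
  if (!is.null(rt)) {
    nr <- rep(NA_integer_, nrow(out))
    idx <- match(round(rt$time_days, 6), round(data$time_days, 6))
    ok <- !is.na(idx)
    nr[idx[ok]] <- rt$n_risk[ok]
    out$n_risk <- nr
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_km_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  rt <- NULL
  if ("n_risk" %in% names(d) && any(!is.na(d$n_risk))) {
    rt <- data.frame(time_days = d$time_days[!is.na(d$n_risk)],
                     n_risk = d$n_risk[!is.na(d$n_risk)])
  }
  km_digitized(d$time_days, d$survival, risk_table = rt)
}
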