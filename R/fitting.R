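flexsurv_dist_name <- function(family) {
  switch(family,
    exponential = "exp",
    weibull = "weibull",
    loglogistic = "llogis",
    lognormal = "lnorm",
    gompertz = "gompertz",
    generalized_gamma = "gengamma",
    stop("unknown family: ", family)
  )
}

curve_from_flexsurv <- function(family, fit) {
  est <- setNames(fit$res[, "est"], rownames(fit$res))
  params <- switch(family,
    exponential = c(rate = unname(est["rate"])),
    weibull = c(shape = unname(est["shape"]), scale = unname(est["scale"])),
    loglogistic = c(shape = unname(est["shape"]),
                    scale = unname(est["scale"])),
    lognormal = c(meanlog = unname(est["meanlog"]),
                  sdlog = unname(est["sdlog"])),
    gompertz = c(shape = unname(est["shape"]), rate = unname(est["rate"])),
    generalized_gamma = c(mu = unname(est["mu"]),
                          sigma = unname(est["sigma"]),
                          Q = unname(est["Q"]))
  )
  parametric_curve(family, params)
}

#' Fit a parametric survival family by maximum likelihood
#'
#' Maximum likelihood under right censoring
#' (log-likelihood = sum over events of log f(t) + sum over censored of
#' log S(t)), via [flexsurv::flexsurvreg()]. If the optimizer fails or does
#' not converge, up to two restarts from jittered initial values are tried;
#' a persistently non-converged fit is returned flagged, never silently.
#'
#' @param data An [ipd_dataset()] with at least one event.
#' @param family One of [supported_families()].
#' @return A `fit_result` list: `curve` ([parametric_curve()]), `loglik`,
#'   `k` (free parameters), `n` (subjects), `aic` (`2k - 2*loglik`), `bic`
#'   (`k*log(n) - 2*loglik`, n = subjects), `converged`, `family`.
#' @examples
#' d <- simulate_arm_ipd("exponential", c(rate = 0.01), n = 100, seed = 1)
#' fit_parametric(d, "exponential")$curve
#' @export
fit_parametric <- function(data, family) {
  stopifnot(inherits(data, "ipd_dataset"))
  family <- match.arg(family, supported_families())
  if (sum(data$event) < 1) stop("cannot fit: dataset has no events")
  df <- data.frame(time = data$time_days, ev = data$event)
  dist <- flexsurv_dist_name(family)
  n <- nrow(df)
  k <- family_n_params(family)

  attempt <- function(inits) {
    args <- list(formula = survival::Surv(time, ev) ~ 1, data = df,
                 dist = dist)
    if (!is.null(inits)) args$inits <- inits
    try(suppressWarnings(do.call(flexsurv::flexsurvreg, args)),
        silent = TRUE)
  }
  fit <- attempt(NULL)
  tries <- 0
  while ((inherits(fit, "try-error") ||
          !isTRUE(fit$opt$convergence == 0)) && tries < 2) {
    tries <- tries + 1
    base_inits <- if (inherits(fit, "try-error")) NULL else fit$res[, "est"]
    inits <- if (is.null(base_inits)) NULL else {
      base_inits * exp(stats::runif(length(base_inits), -0.2, 0.2))
    }
    fit2 <- attempt(inits)
    if (!inherits(fit2, "try-error") &&
        (inherits(fit, "try-error") || fit2$loglik >= fit$loglik)) {
      fit <- fit2
    }
  }
  if (inherits(fit, "try-error")) {
    return(structure(list(curve = NULL, loglik = NA_real_, k = k, n = n,
                          aic = NA_real_, bic = NA_real_, converged = FALSE,
                          family = family),
                     class = "fit_result"))
  }
  ll <- fit$loglik
  converged <- isTRUE(fit$opt$convergence == 0) && is.finite(ll)
  structure(list(curve = curve_from_flexsurv(family, fit),
                 loglik = ll, k = k, n = n,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 converged = converged, family = family),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: loglik %.3f, AIC %.2f, BIC %.2f (%s)\n",
              x$family, x$loglik, x$aic, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit all six parametric families
#'
#' @inheritParams fit_parametric
#' @param families Families to fit (default all six).
#' @return A named list of `fit_result` objects.
#' @export
fit_all_families <- function(data, families = supported_families()) {
  setNames(lapply(families, function(f) fit_parametric(data, f)), families)
}

#' Information-criterion table for a set of fits
#'
#' @param fits A list of `fit_result` objects (e.g. [fit_all_families()]).
#' @return Data frame with columns `family`, `loglik`, `k`, `aic`, `bic`,
#'   `converged`.
#' @export
criterion_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$family, loglik = f$loglik, k = f$k,
               aic = f$aic, bic = f$bic, converged = f$converged,
               stringsAsFactors = FALSE)
  })) -> tab
  rownames(tab) <- NULL
  tab
}

#' Select the best-fitting family by AIC or BIC
#'
#' Returns the converged fit minimizing the chosen criterion. Ties are
#' broken toward the family with fewer parameters, then by family name, for
#' reproducibility.
#'
#' @param fits A list of `fit_result` objects.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return The chosen `fit_result`, with the full criterion table attached
#'   as `attr(, "criterion_table")`.
#' @export
select_model <- function(fits, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (inherits(fits, "fit_result")) fits <- list(fits)
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(ok) == 0) stop("no converged fits to select from")
  crit <- vapply(ok, function(f) if (criterion == "AIC") f$aic else f$bic,
                 numeric(1))
  ks <- vapply(ok, function(f) f$k, integer(1))
  fams <- vapply(ok, function(f) f$family, character(1))
  best <- ok[[order(crit, ks, fams)[1]]]
  attr(best, "criterion_table") <- criterion_table(fits)
  best
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Interval-wise Guyot-style reconstruction: event counts are recovered by
#' inverting the product-limit identity over the digitized survival drops;
#' with a numbers-at-risk table, censorings are allocated uniformly within
#' each risk interval and adjusted iteratively so the reconstructed at-risk
#' counts match the table. Without a risk table, censoring is assumed to
#' occur only at the end of follow-up.
#'
#' @param curve A [km_digitized()] object; a risk table attribute is used
#'   when present.
#' @param n_start Initial number at risk when no risk table is supplied
#'   (default 100).
#' @param arm,endpoint Labels for the output dataset.
#' @return An [ipd_dataset()] whose KM estimate reproduces the digitized
#'   coordinates (within rounding at the chosen cohort size).
#' @examples
#' km <- km_digitized(c(0, 100, 200), c(1, 0.6, 0.3))
#' d <- reconstruct_ipd_from_km(km, n_start = 50)
#' @export
reconstruct_ipd_from_km <- function(curve, n_start = 100, arm = "arm",
                                    endpoint = "OS") {
  stopifnot(inherits(curve, "km_digitized"))
  tt <- curve$time_days
  ss <- curve$survival
  if (tt[1] > 0) { tt <- c(0, tt); ss <- c(1, ss) }
  if (ss[1] > 1 + 1e-9) stop("survival at time 0 must be <= 1")
  if (any(diff(ss) > 1e-12)) stop("survival must be non-increasing")
  if (all(abs(diff(ss)) < 1e-12)) {
    stop("flat digitized curve: no events to place")
  }
  rt <- attr(curve, "risk_table")
  m <- length(tt)

  if (is.null(rt)) {
    # no risk table: censoring only at curve end
    n0 <- n_start
    alive <- round(n0 * ss / ss[1])
    d <- -diff(alive)
    d[d < 0] <- 0
    times <- rep(tt[-1], d)
    events <- rep(1L, length(times))
    n_left <- n0 - sum(d)
    if (n_left > 0) {
      times <- c(times, rep(max(tt), n_left))
      events <- c(events, rep(0L, n_left))
    }
    if (sum(events) == 0) stop("reconstruction produced no events")
    return(ipd_dataset(times, events, arm, endpoint))
  }

  # Guyot-type allocation with a risk table
  keep_rt <- rt$time_days <= max(tt) + 1e-9
  trisk <- rt$time_days[keep_rt]
  nrisk <- rt$n_risk[keep_rt]
  if (length(trisk) == 0 || nrisk[1] <= 0) {
    stop("risk table does not overlap the digitized curve")
  }
  J <- length(trisk)
  lower <- vapply(seq_len(J), function(j) {
    which(tt >= trisk[j] - 1e-9)[1]
  }, integer(1))
  upper <- c(lower[-1] - 1L, m)

  n_hat <- numeric(m); n_hat[lower[1]] <- nrisk[1]
  d_i <- integer(m); c_i <- numeric(m); ct_i <- vector("list", m)
  km_last <- 1; s_last <- ss[lower[1]]

  for (j in seq_len(J)) {
    lo <- lower[j]; up <- upper[j]
    ncen <- if (j < J) {
      max(0, round(n_hat[lo] * ss[lower[j + 1]] / max(ss[lo], 1e-12)) -
            nrisk[j + 1])
    } else {
      0
    }
    repeat {
      # distribute censor times uniformly over the interval
      cen_times <- if (ncen > 0) {
        t_end <- if (j < J) trisk[j + 1] else max(tt)
        trisk[j] + (seq_len(ncen) - 0.5) / ncen * (t_end - trisk[j])
      } else numeric(0)
      nh <- n_hat[lo]; kml <- km_last
      for (i in lo:up) {
        d_i[i] <- if (kml > 0 && nh > 0) {
          max(0, round(nh * (1 - ss[i] / kml)))
        } else 0
        if (d_i[i] > 0 && nh > 0) {
          kml <- kml * (1 - d_i[i] / nh)
        }
        nc <- sum(cen_times >= tt[i] &
                  cen_times < (if (i < m) tt[i + 1] else Inf))
        c_i[i] <- nc
        ct_i[[i]] <- cen_times[cen_times >= tt[i] &
                               cen_times < (if (i < m) tt[i + 1] else Inf)]
        nh <- nh - d_i[i] - nc
        if (i < m) n_hat[i + 1] <- nh
      }
      if (j == J) { km_last <- kml; break }
      discrepancy <- n_hat[lower[j + 1]] - nrisk[j + 1]
      if (discrepancy == 0 || (discrepancy < 0 && ncen == 0)) {
        km_last <- kml
        break
      }
      ncen_new <- ncen + discrepancy
      if (ncen_new < 0) ncen_new <- 0
      if (ncen_new == ncen) { km_last <- kml; break }
      ncen <- ncen_new
    }
  }

  times <- c(rep(tt, d_i),
             unlist(ct_i[lengths(ct_i) > 0], use.names = FALSE))
  events <- c(rep(1L, sum(d_i)), rep(0L, sum(lengths(ct_i))))
  n_left <- nrisk[1] - length(times)
  if (n_left > 0) {
    times <- c(times, rep(max(tt), n_left))
    events <- c(events, rep(0L, n_left))
  }
  if (sum(events) == 0) stop("reconstruction produced no events")
  keep <- times > 0
  ipd_dataset(times[keep], events[keep], arm, endpoint)
}

#' Write a criterion table as CSV
#'
#' @param fits List of `fit_result` objects or a criterion-table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_criterion_csv <- function(fits, path) {
  tab <- if (is.data.frame(fits)) fits else criterion_table(fits)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
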