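#' @importFrom stats pexp pweibull plnorm qexp qweibull qlnorm rexp rweibull
#'   rlnorm dexp dweibull dlnorm pnorm qnorm runif approxfun setNames
NULL

# One month = 30.4375 days (365.25 / 12); the model mixes 21-day cycles,
# month-scale medians and year-scale horizons, so days are the internal unit.
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Convert months to days
#'
#' The package works internally in days; published survival medians are in
#' months. One month is 365.25/12 = 30.4375 days.
#'
#' @param months Numeric vector of durations in months.
#' @return Durations in days.
#' @export
months_to_days <- function(months) months * DAYS_PER_MONTH

#' @rdname months_to_days
#' @param days Numeric vector of durations in days.
#' @export
days_to_months <- function(days) days / DAYS_PER_MONTH

#' Supported parametric survival families
#'
#' The six families used for survival extrapolation: exponential, Weibull,
#' log-logistic, lognormal, Gompertz and generalized gamma.
#'
#' @return Character vector of family names.
#' @export
supported_families <- function() {
  c("exponential", "weibull", "loglogistic", "lognormal",
    "gompertz", "generalized_gamma")
}

# free parameters per family (used for AIC/BIC)
family_n_params <- function(family) {
  switch(family,
    exponential = 1L,
    weibull = 2L,
    loglogistic = 2L,
    lognormal = 2L,
    gompertz = 2L,
    generalized_gamma = 3L,
    stop("unknown family: ", family)
  )
}

family_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    loglogistic = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    gompertz = c("shape", "rate"),
    generalized_gamma = c("mu", "sigma", "Q"),
    stop("unknown family: ", family)
  )
}

validate_family_params <- function(family, params) {
  pn <- family_param_names(family)
  if (length(params) != length(pn)) {
    stop(sprintf("family '%s' needs %d parameter(s) (%s), got %d",
                 family, length(pn), paste(pn, collapse = ", "),
                 length(params)))
  }
  if (is.null(names(params)) || !all(nzchar(names(params)))) {
    names(params) <- pn
  }
  params <- params[pn]
  if (anyNA(params) || any(!is.finite(params))) {
    stop("parameters must be finite, non-missing values")
  }
  positive <- switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    loglogistic = c("shape", "scale"),
    lognormal = "sdlog",
    gompertz = "rate",        # shape may be any real (including 0)
    generalized_gamma = "sigma"
  )
  bad <- positive[params[positive] <= 0]
  if (length(bad)) {
    stop(sprintf("family '%s': parameter(s) %s must be strictly positive",
                 family, paste(bad, collapse = ", ")))
  }
  params
}

#' Construct a parametric survival curve
#'
#' A `parametric_curve` bundles a survival family with a parameter vector on
#' the day scale and supports survival, hazard, density and quantile
#' evaluation as well as random generation.
#'
#' Parameterizations (t in days):
#' \itemize{
#'   \item exponential: `S(t) = exp(-rate * t)`
#'   \item weibull: `S(t) = exp(-(t/scale)^shape)`
#'   \item loglogistic: `S(t) = 1 / (1 + (t/scale)^shape)`
#'   \item lognormal: `S(t) = 1 - Phi((log t - meanlog)/sdlog)`
#'   \item gompertz: `S(t) = exp(-(rate/shape) * (exp(shape*t) - 1))`
#'   \item generalized_gamma: location (`mu`), scale (`sigma`), shape (`Q`)
#'     form; `Q = 0` is the lognormal limit (values with `|Q| < 1e-5` are
#'     evaluated with the lognormal formula for numerical stability).
#' }
#'
#' @param family One of [supported_families()].
#' @param params Named numeric vector of family parameters (day scale).
#' @param scale Time-unit tag; only `"days"` is used internally.
#' @return An object of class `parametric_curve`.
#' @examples
#' cv <- parametric_curve("exponential", c(rate = log(2) / 365))
#' survival_at(cv, 365)  # 0.5 at the median
#' @export
parametric_curve <- function(family, params, scale = "days") {
  family <- match.arg(family, supported_families())
  params <- validate_family_params(family, params)
  structure(list(family = family, params = params, scale = scale),
            class = "parametric_curve")
}

#' @export
print.parametric_curve <- function(x, ...) {
  cat(sprintf("<parametric_curve> %s (%s)\n", x$family, x$scale))
  print(round(x$params, 6))
  invisible(x)
}

GG_LNORM_EPS <- 1e-5  # |Q| below this: use the lognormal limit

#' Evaluate a survival curve
#'
#' @param curve A [parametric_curve()], an adjusted-survival object from
#'   [apply_background_mortality()], or a plain function of time in days.
#' @param t Times in days (non-negative).
#' @return Survival fractions in `[0, 1]`.
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop("survival_at: t must be non-negative")
  if (is.function(curve)) return(pmin(1, pmax(0, curve(t))))
  if (inherits(curve, "adjusted_survival")) return(curve$surv(t))
  stopifnot(inherits(curve, "parametric_curve"))
  p <- curve$params
  s <- switch(curve$family,
    exponential = exp(-p[["rate"]] * t),
    weibull = pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal = plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, p[["shape"]], p[["rate"]],
                                   lower.tail = FALSE),
    generalized_gamma = {
      if (abs(p[["Q"]]) < GG_LNORM_EPS) {
        plnorm(t, p[["mu"]], p[["sigma"]], lower.tail = FALSE)
      } else {
        flexsurv::pgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]],
                            lower.tail = FALSE)
      }
    }
  )
  pmin(1, pmax(0, s))
}

#' Evaluate the density of a survival curve
#'
#' @inheritParams survival_at
#' @return Density values.
#' @export
density_at <- function(curve, t) {
  stopifnot(inherits(curve, "parametric_curve"))
  if (any(t < 0)) stop("density_at: t must be non-negative")
  p <- curve$params
  switch(curve$family,
    exponential = dexp(t, p[["rate"]]),
    weibull = dweibull(t, p[["shape"]], p[["scale"]]),
    loglogistic = flexsurv::dllogis(t, p[["shape"]], p[["scale"]]),
    lognormal = dlnorm(t, p[["meanlog"]], p[["sdlog"]]),
    gompertz = flexsurv::dgompertz(t, p[["shape"]], p[["rate"]]),
    generalized_gamma = {
      if (abs(p[["Q"]]) < GG_LNORM_EPS) {
        dlnorm(t, p[["mu"]], p[["sigma"]])
      } else {
        flexsurv::dgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]])
      }
    }
  )
}

#' Evaluate the hazard of a survival curve
#'
#' Hazard `h(t) = f(t) / S(t)`, in events per day.
#'
#' @inheritParams survival_at
#' @return Hazard values per day.
#' @export
hazard_at <- function(curve, t) {
  s <- survival_at(curve, t)
  f <- density_at(curve, t)
  ifelse(s > 0, f / s, Inf)
}

# quantile of the time distribution at probability p (of failure)
quantile_surv <- function(curve, p) {
  stopifnot(inherits(curve, "parametric_curve"))
  pr <- curve$params
  switch(curve$family,
    exponential = qexp(p, pr[["rate"]]),
    weibull = qweibull(p, pr[["shape"]], pr[["scale"]]),
    loglogistic = flexsurv::qllogis(p, pr[["shape"]], pr[["scale"]]),
    lognormal = qlnorm(p, pr[["meanlog"]], pr[["sdlog"]]),
    gompertz = flexsurv::qgompertz(p, pr[["shape"]], pr[["rate"]]),
    generalized_gamma = flexsurv::qgengamma(p, pr[["mu"]], pr[["sigma"]],
                                            pr[["Q"]])
  )
}

# random event times from a curve (uses the session RNG stream)
random_times <- function(curve, n) {
  quantile_surv(curve, runif(n))
}

#' Calibrate a curve from a published median
#'
#' When only a published median survival is available, an exponential curve
#' is fixed by `rate = log(2) / median` and a lognormal by
#' `meanlog = log(median)` with a supplied `sdlog`. Either way
#' `S(median) = 0.5` exactly.
#'
#' @param family `"exponential"` or `"lognormal"`.
#' @param median Median survival (in `unit`).
#' @param sigma Lognormal `sdlog` (required for the lognormal family).
#' @param unit Unit of `median`: `"months"` (default) or `"days"`.
#' @return A [parametric_curve()] on the day scale.
#' @examples
#' cv <- curve_from_median("exponential", 17.2)
#' survival_at(cv, months_to_days(17.2))  # exactly 0.5
#' @export
curve_from_median <- function(family, median, sigma = NULL,
                              unit = c("months", "days")) {
  unit <- match.arg(unit)
  if (!is.numeric(median) || length(median) != 1 || median <= 0) {
    stop("median must be a single positive number")
  }
  med_days <- if (unit == "months") months_to_days(median) else median
  switch(family,
    exponential = parametric_curve("exponential",
                                   c(rate = log(2) / med_days)),
    lognormal = {
      if (is.null(sigma) || sigma <= 0) {
        stop("lognormal calibration needs sigma > 0")
      }
      parametric_curve("lognormal",
                       c(meanlog = log(med_days), sdlog = sigma))
    },
    stop("curve_from_median supports only exponential and lognormal, got '",
         family, "'")
  )
}
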