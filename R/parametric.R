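DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

.surv_families <- c("exponential", "weibull", "gamma", "gompertz",
                    "lognormal", "loglogistic")

.flexsurv_dist <- c(exponential = "exp", weibull = "weibull", gamma = "gamma",
                    gompertz = "gompertz", lognormal = "lnorm",
                    loglogistic = "llogis")

#' Parametric survival model
#'
#' A fitted (or directly specified) parametric survival family supporting
#' survival-function queries, per-cycle probabilities and hazard-ratio
#' application. Families use the usual parameterisations: `exponential(rate)`,
#' `weibull(shape, scale)`, `gamma(shape, rate)`, `gompertz(shape, rate)`,
#' `lognormal(meanlog, sdlog)`, `loglogistic(shape, scale)`.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`.
#' @param params Named numeric vector of family parameters.
#' @param log_likelihood,aic Fit statistics (NA when the model was specified
#'   rather than fitted).
#' @param time_unit Time unit of `t` in `S(t)`: `"months"` (default) or
#'   `"years"`.
#' @return An object of class `parametric_survival`.
#' @export
#' @examples
#' m <- parametric_survival("exponential", c(rate = 0.08))
#' surv_prob(m, c(0, 10))
parametric_survival <- function(family, params, log_likelihood = NA_real_,
                                aic = NA_real_, time_unit = "months") {
  family <- match.arg(family, .surv_families)
  time_unit <- match.arg(time_unit, c("months", "years"))
  need <- switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    gamma = c("shape", "rate"),
    gompertz = c("shape", "rate"),
    lognormal = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"))
  if (!all(need %in% names(params)))
    stop("family '", family, "' needs parameters: ", paste(need, collapse = ", "))
  params <- params[need]
  pos <- setdiff(need, c("meanlog", "shape")[c(TRUE, family == "gompertz")])
  if (any(params[pos] <= 0))
    stop("parameters ", paste(pos, collapse = ", "), " must be positive")
  structure(list(family = family, params = params,
                 log_likelihood = log_likelihood, aic = aic,
                 time_unit = time_unit),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("Parametric survival model: ", x$family, "\n  ",
      paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", "),
      "\n", sep = "")
  if (is.finite(x$aic))
    cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$log_likelihood, x$aic))
  invisible(x)
}

#' Survival function of a parametric model
#'
#' @param model A [parametric_survival()] object.
#' @param t Times in the model's time unit.
#' @return `S(t)`, with `S(0) = 1`.
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  p <- model$params
  switch(model$family,
    exponential = stats::pexp(t, rate = p["rate"], lower.tail = FALSE),
    weibull = stats::pweibull(t, shape = p["shape"], scale = p["scale"],
                              lower.tail = FALSE),
    gamma = stats::pgamma(t, shape = p["shape"], rate = p["rate"],
                          lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p["shape"], rate = p["rate"],
                                   lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = p["meanlog"], sdlog = p["sdlog"],
                              lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p["shape"], scale = p["scale"],
                                    lower.tail = FALSE))
}

#' Fit a parametric survival family to right-censored pseudo-IPD
#'
#' Maximum-likelihood fitting (via flexsurv) of one of the six supported
#' families to right-censored event-time data.
#'
#' @param ipd A [pseudo_ipd()] object (times in months) with at least 2 events.
#' @param family Family name, see [parametric_survival()].
#' @return A [parametric_survival()] with `log_likelihood` and `aic` filled in
#'   (`aic = 2k - 2 logLik`).
#' @export
fit_parametric <- function(ipd, family) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  family <- match.arg(family, .surv_families)
  if (sum(ipd$event) < 2L)
    stop("fitting requires at least 2 events (got ", sum(ipd$event), ")")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = .flexsurv_dist[[family]]),
    error = function(e) stop("fit of family '", family, "' failed: ",
                             conditionMessage(e), call. = FALSE))
  est <- fit$res[, "est"]
  names(est) <- rownames(fit$res)
  ll <- as.numeric(stats::logLik(fit))
  parametric_survival(family, est, log_likelihood = ll,
                      aic = 2 * length(est) - 2 * ll)
}

#' Fit several families and select the best by AIC
#'
#' Fits each candidate family with [fit_parametric()]; individual fit failures
#' are collected as warnings unless every family fails. The fit with minimal
#' AIC is returned; ties are broken by fewer parameters, then by the order of
#' `families`.
#'
#' @inheritParams fit_parametric
#' @param families Character vector of candidate families.
#' @return The selected [parametric_survival()].
#' @export
select_best <- function(ipd, families = .surv_families) {
  if (length(families) < 1L) stop("at least one candidate family is required")
  fits <- vector("list", length(families))
  errs <- character(0)
  for (i in seq_along(families)) {
    fits[[i]] <- tryCatch(fit_parametric(ipd, families[i]), error = function(e) {
      errs <<- c(errs, conditionMessage(e))
      NULL
    })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all candidate families failed to fit:\n  ",
         paste(errs, collapse = "\n  "))
  if (length(errs))
    warning("some families failed to fit: ", paste(errs, collapse = "; "))
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, function(f) length(f$params), numeric(1))
  fits[[order(aic, k, seq_along(fits))[1]]]
}

#' Per-cycle event probability from a survival model
#'
#' Conditional probability of the event during cycle `cycle_index`, i.e.
#' `1 - S(t1)/S(t0)` with `t0 = cycle_index * cycle_days` and
#' `t1 = t0 + cycle_days`, converted to the model's time unit.
#'
#' @param model A [parametric_survival()].
#' @param cycle_index Non-negative integer cycle index (vectorised).
#' @param cycle_days Cycle length in days (default 28).
#' @return Probability in `[0, 1)`; 1 (with a warning) where `S(t0) = 0`.
#' @export
cycle_probability <- function(model, cycle_index, cycle_days = 28) {
  if (any(cycle_index < 0)) stop("cycle_index must be non-negative")
  if (cycle_days <= 0) stop("cycle_days must be positive")
  per_unit <- if (model$time_unit == "months") DAYS_PER_MONTH else DAYS_PER_YEAR
  t0 <- cycle_index * cycle_days / per_unit
  s0 <- surv_prob(model, t0)
  s1 <- surv_prob(model, t0 + cycle_days / per_unit)
  p <- ifelse(s0 > 0, 1 - s1 / s0, 1)
  if (any(s0 == 0))
    warning("S(t0) = 0 for some cycles; returning probability 1 there")
  pmin(pmax(p, 0), 1)
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Converts a per-cycle probability to the hazard scale (constant hazard
#' within the cycle), multiplies by the hazard ratio, and converts back:
#' `1 - (1 - p)^hr`.
#'
#' @param p Per-cycle probability in `[0, 1)` (vectorised).
#' @param hr Positive hazard ratio.
#' @return Adjusted probability in `[0, 1)`.
#' @export
#' @examples
#' apply_hazard_ratio(0.0854, 0.21)
apply_hazard_ratio <- function(p, hr) {
  if (any(hr <= 0)) stop("hazard ratio must be positive")
  if (any(p < 0 | p >= 1))
    stop("probability must lie in [0, 1): the hazard is undefined at p = 1")
  1 - (1 - p)^hr
}

#' Hazard-ratio set of the case study
#'
#' @param hr_pfs HR for progression-free survival (intervention vs control).
#' @param hr_os HR for overall survival (intervention vs control).
#' @param hr_sd_vs_pd HR for overall survival in SD vs PD.
#' @param ci Optional named list of `c(lower, upper)` 95% CI bounds.
#' @return An object of class `hazard_ratio_set`.
#' @export
hazard_ratio_set <- function(hr_pfs, hr_os, hr_sd_vs_pd, ci = list()) {
  hrs <- c(hr_pfs = hr_pfs, hr_os = hr_os, hr_sd_vs_pd = hr_sd_vs_pd)
  if (any(hrs <= 0)) stop("all hazard ratios must be positive")
  for (nm in names(ci)) {
    b <- ci[[nm]]
    if (!(b[1] < hrs[[nm]] && hrs[[nm]] < b[2]))
      stop("CI bounds for ", nm, " must bracket the mean")
  }
  structure(list(hr_pfs = hr_pfs, hr_os = hr_os, hr_sd_vs_pd = hr_sd_vs_pd,
                 ci = ci), class = "hazard_ratio_set")
}

#' Write a fit summary table
#'
#' @param fits List of [parametric_survival()] objects.
#' @param file Output CSV path.
#' @return The summary data.frame, invisibly.
#' @export
write_fit_summary <- function(fits, file) {
  rows <- lapply(fits, function(f) {
    data.frame(family = f$family,
               params = paste(sprintf("%s=%.6g", names(f$params), f$params),
                              collapse = ";"),
               loglik = f$log_likelihood, aic = f$aic)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
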