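#' Digitized Kaplan-Meier curve with numbers at risk
#'
#' Container for coordinates read off a published Kaplan-Meier plot together
#' with the numbers-at-risk table printed beneath it. This pair is the raw
#' material for pseudo individual-patient-data reconstruction with
#' [reconstruct_ipd()].
#'
#' @param time Numeric vector of curve times (months), starting at 0.
#' @param survival Numeric vector of survival fractions in `[0, 1]`,
#'   non-increasing, starting at 1.
#' @param risk_time Numeric vector of risk-table times (months).
#' @param n_risk Integer vector of numbers at risk, non-increasing.
#' @param label Curve label (e.g. `"OS control"`).
#'
#' @return An object of class `digitized_km` with components `curve`
#'   (data.frame `time`, `survival`), `risk` (data.frame `time`, `n_risk`)
#'   and `label`.
#' @export
#' @examples
#' km <- digitized_km(c(0, 2, 5), c(1, 0.8, 0.4),
#'                    risk_time = c(0, 6), n_risk = c(10, 4))
digitized_km <- function(time, survival, risk_time, n_risk, label = "") {
  stopifnot(length(time) == length(survival),
            length(risk_time) == length(n_risk))
  if (length(time) < 2L)
    stop("digitized curve needs at least 2 points")
  if (any(time < 0) || any(risk_time < 0))
    stop("times must be non-negative")
  if (is.unsorted(time, strictly = TRUE))
    stop("curve times must be strictly increasing")
  if (is.unsorted(risk_time, strictly = TRUE))
    stop("risk-table times must be strictly increasing")
  if (abs(time[1]) > 1e-9 || abs(survival[1] - 1) > 1e-9)
    stop("curve must start at (0, 1)")
  if (any(survival < 0 | survival > 1))
    stop("survival fractions must lie in [0, 1]")
  up <- which(diff(survival) > 1e-9)
  if (length(up))
    stop("survival must be non-increasing; it increases after t = ",
         time[up[1]])
  if (any(diff(n_risk) > 0))
    stop("risk-table counts must be non-increasing")
  if (any(n_risk < 0) || any(n_risk != round(n_risk)))
    stop("numbers at risk must be non-negative integers")
  structure(
    list(curve = data.frame(time = as.numeric(time),
                            survival = as.numeric(survival)),
         risk  = data.frame(time = as.numeric(risk_time),
                            n_risk = as.integer(n_risk)),
         label = label),
    class = "digitized_km")
}

#' @export
print.digitized_km <- function(x, ...) {
  cat("Digitized Kaplan-Meier curve", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n  ", nrow(x$curve), " digitized points over [0, ",
      max(x$curve$time), "] months\n  risk table: ",
      paste(sprintf("%g (n=%d)", x$risk$time, x$risk$n_risk), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a digitized curve and its risk table from CSV files
#'
#' @param curve_file CSV with header `time,survival`.
#' @param risk_file CSV with header `time,n_risk`.
#' @param label Curve label.
#' @return A [digitized_km()] object.
#' @export
read_digitized_km <- function(curve_file, risk_file, label = "") {
  cv <- utils::read.csv(curve_file)
  rk <- utils::read.csv(risk_file)
  if (!all(c("time", "survival") %in% names(cv)))
    stop("curve file must have columns time,survival")
  if (!all(c("time", "n_risk") %in% names(rk)))
    stop("risk file must have columns time,n_risk")
  digitized_km(cv$time, cv$survival, rk$time, rk$n_risk, label = label)
}

#' Write a digitized curve and risk table to CSV files
#'
#' @param km A [digitized_km()] object.
#' @param curve_file,risk_file Output paths.
#' @return Invisibly, `km`.
#' @export
write_digitized_km <- function(km, curve_file, risk_file) {
  utils::write.csv(km$curve, curve_file, row.names = FALSE)
  utils::write.csv(km$risk, risk_file, row.names = FALSE)
  invisible(km)
}
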