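#' Run the Markov cohort simulation
#'
#' Iterates the cohort through the per-cycle transition matrices. State
#' membership is counted at cycle start (no half-cycle correction). The trace
#' ends at the first cycle where more than 99% of the cohort is in the
#' absorbing state, or at the end of the schedule (the schedule itself is
#' capped at a 60-year horizon when built by the pipeline).
#'
#' @param schedule A [transition_schedule()].
#' @param start Occupancy vector `(SD, PD, Dead)` summing to 1.
#' @param start_age Cohort age at cycle 0 (years), recorded in the trace.
#' @param absorb_threshold Dead fraction above which the trace terminates.
#' @return A `cohort_trace`: data.frame with columns `cycle`, `age`, `occ_sd`,
#'   `occ_pd`, `occ_dead`, `new_deaths`, with the cycle length stored as the
#'   `cycle_days` attribute.
#' @export
run_cohort <- function(schedule, start = c(1, 0, 0), start_age = 63,
                       absorb_threshold = 0.99) {
  stopifnot(inherits(schedule, "transition_schedule"))
  if (abs(sum(start) - 1) > 1e-9) stop("start occupancy must sum to 1")
  if (any(start < 0)) stop("start occupancy must be non-negative")
  n <- schedule$n_cycles
  cd <- schedule$cycle_days
  occ_sd <- occ_pd <- occ_dead <- new_deaths <- numeric(n + 1)
  sd <- start[1]; pd <- start[2]; dead <- start[3]
  last <- n
  for (i in seq_len(n + 1)) {
    occ_sd[i] <- sd; occ_pd[i] <- pd; occ_dead[i] <- dead
    new_deaths[i] <- if (i == 1) 0 else dead - occ_dead[i - 1]
    if (dead > absorb_threshold || i == n + 1) { last <- i; break }
    p1 <- schedule$p_sd_pd[i]; p2 <- schedule$p_sd_d[i]; p3 <- schedule$p_pd_d[i]
    sd_new <- sd * (1 - p1 - p2)
    pd_new <- pd * (1 - p3) + sd * p1
    dead <- 1 - sd_new - pd_new
    sd <- sd_new; pd <- pd_new
  }
  idx <- seq_len(last)
  out <- data.frame(cycle = idx - 1L,
                    age = start_age + (idx - 1) * cd / DAYS_PER_YEAR,
                    occ_sd = occ_sd[idx], occ_pd = occ_pd[idx],
                    occ_dead = occ_dead[idx], new_deaths = new_deaths[idx])
  structure(out, cycle_days = cd, start_age = start_age,
            strategy = schedule$strategy,
            class = c("cohort_trace", "data.frame"))
}

#' Write a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param file Output CSV path.
#' @return `trace`, invisibly.
#' @export
write_trace <- function(trace, file) {
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  invisible(trace)
}

#' Median survival time implied by a cohort trace
#'
#' Linear interpolation of the first crossing of 50% cumulative mortality.
#'
#' @param trace A `cohort_trace`.
#' @return Time in months (NA if mortality never reaches 50%).
#' @export
trace_median_survival <- function(trace) {
  cd <- attr(trace, "cycle_days")
  i <- which(trace$occ_dead >= 0.5)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  d0 <- trace$occ_dead[i - 1]; d1 <- trace$occ_dead[i]
  frac <- (0.5 - d0) / (d1 - d0)
  ((i - 2) + frac) * cd / DAYS_PER_MONTH
}
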