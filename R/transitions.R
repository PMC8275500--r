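#' Per-cycle transition schedule for one strategy
#'
#' Holds the per-cycle probabilities of the three possible transitions of the
#' model (SD to PD, SD to dead, PD to dead); dead is absorbing and PD cannot
#' return to SD. Rows of the implied 3x3 matrices are stochastic by
#' construction.
#'
#' @param p_sd_pd,p_sd_d,p_pd_d Numeric vectors (one element per cycle) of
#'   transition probabilities.
#' @param strategy Strategy label (`"control"` or `"intervention"`).
#' @param cycle_days Cycle length in days.
#' @param override_cycle Optional: first cycle index at which background
#'   mortality replaced the disease-specific probability (diagnostics).
#' @return A `transition_schedule` object.
#' @export
transition_schedule <- function(p_sd_pd, p_sd_d, p_pd_d, strategy,
                                cycle_days = 28, override_cycle = NULL) {
  n <- length(p_sd_pd)
  stopifnot(length(p_sd_d) == n, length(p_pd_d) == n)
  if (any(p_sd_pd < 0 | p_sd_d < 0 | p_pd_d < 0 | p_sd_d > 1 | p_pd_d > 1))
    stop("transition probabilities must lie in [0, 1]")
  if (any(p_sd_pd + p_sd_d > 1 + 1e-12))
    stop("SD row exceeds 1: p(SD->PD) + p(SD->dead) > 1 at some cycle")
  structure(list(p_sd_pd = p_sd_pd, p_sd_d = p_sd_d, p_pd_d = p_pd_d,
                 strategy = strategy, cycle_days = cycle_days,
                 n_cycles = n, override_cycle = override_cycle),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("Transition schedule (", x$strategy, "): ", x$n_cycles, " cycles of ",
      x$cycle_days, " days\n", sep = "")
  cat(sprintf("  cycle 0: p(SD->PD) = %.4f, p(SD->D) = %.4f, p(PD->D) = %.4f\n",
              x$p_sd_pd[1], x$p_sd_d[1], x$p_pd_d[1]))
  if (!is.null(x$override_cycle))
    cat("  background-mortality override from cycle", x$override_cycle, "\n")
  invisible(x)
}

#' Extract the 3x3 transition matrix of one cycle
#'
#' States are ordered (SD, PD, Dead); Dead is absorbing.
#'
#' @param x A [transition_schedule()].
#' @param cycle Cycle index (0-based).
#' @param ... Unused.
#' @return A row-stochastic 3x3 matrix.
#' @export
as.matrix.transition_schedule <- function(x, cycle = 0, ...) {
  i <- cycle + 1L
  stopifnot(i >= 1L, i <= x$n_cycles)
  m <- matrix(c(1 - x$p_sd_pd[i] - x$p_sd_d[i], x$p_sd_pd[i], x$p_sd_d[i],
                0, 1 - x$p_pd_d[i], x$p_pd_d[i],
                0, 0, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("SD", "PD", "Dead"), c("SD", "PD", "Dead")))
  m
}

# Permanent background-mortality override: from the first cycle where the
# life-table probability exceeds the disease-specific one, the life-table
# probability is used for all later cycles. Increasing-hazard models start
# near zero, so only crossings after disease mortality has risen above the
# background count; an early spurious crossing would otherwise lock the whole
# model to the life table. `per_cycle_max = TRUE` instead takes the cyclewise
# maximum everywhere (scenario flag).
.override_cycle <- function(p_model, p_bg) {
  above <- which(p_model > p_bg)
  if (!length(above)) return(1L)   # background dominates throughout
  k <- which(p_bg > p_model)
  k <- k[k > above[1]]
  if (!length(k)) return(NULL)
  k[1]
}

.override_mortality <- function(p_model, p_bg, per_cycle_max = FALSE) {
  if (per_cycle_max) {
    return(list(p = pmax(p_model, p_bg), cross = 0L))
  }
  k <- .override_cycle(p_model, p_bg)
  if (is.null(k)) return(list(p = p_model, cross = NULL))
  p <- p_model
  p[k:length(p)] <- p_bg[k:length(p)]
  list(p = p, cross = k - 1L)
}

#' Solve the SD/PD split of an overall death probability
#'
#' Given the occupancy shares among the alive and the overall per-cycle death
#' probability, finds per-state death probabilities whose hazards are in the
#' ratio `hr_sd_vs_pd` (SD vs PD) and whose occupancy-weighted mean equals the
#' overall probability. Solved by bisection on the PD hazard (tolerance
#' 1e-12).
#'
#' @param p_os Overall per-cycle death probability among the alive.
#' @param w_sd Share of the alive cohort in SD (the PD share is `1 - w_sd`).
#' @param hr_sd_vs_pd Hazard ratio of death in SD vs PD (< 1: SD safer).
#' @return List with `p_sd` and `p_pd`.
#' @export
split_death_probability <- function(p_os, w_sd, hr_sd_vs_pd) {
  stopifnot(p_os >= 0, p_os < 1, w_sd >= 0, w_sd <= 1, hr_sd_vs_pd > 0)
  if (p_os == 0) return(list(p_sd = 0, p_pd = 0))
  f <- function(h_pd) {
    w_sd * (1 - exp(-hr_sd_vs_pd * h_pd)) +
      (1 - w_sd) * (1 - exp(-h_pd)) - p_os
  }
  hi <- 1
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) < 0) {  # no solution in [0, 1): clamp
    warning("death-split has no solution; clamping per-state probabilities")
    return(list(p_sd = min(p_os, 1 - 1e-12), p_pd = min(p_os, 1 - 1e-12)))
  }
  lo <- 0
  while (hi - lo > 1e-12 * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  h_pd <- (lo + hi) / 2
  list(p_sd = 1 - exp(-hr_sd_vs_pd * h_pd), p_pd = 1 - exp(-h_pd))
}

#' Build a transition schedule from fitted survival curves
#'
#' Derives per-cycle transition probabilities for one strategy from
#' progression-free and overall survival models fitted on the control arm.
#' For the intervention strategy the PFS and OS hazard ratios are applied via
#' [apply_hazard_ratio()]. Each cycle's overall death probability is split
#' between SD and PD with [split_death_probability()], using the occupancy of
#' the evolving cohort as weights, so that the occupancy-weighted death
#' probability among the alive reproduces the OS curve. The SD-to-PD
#' probability is the PFS event probability net of SD death,
#' `max(0, p_pfs - p_sd_death)`. From the first cycle where the life-table
#' background mortality exceeds the model's overall death probability, the
#' life-table probability replaces both per-state death probabilities
#' permanently.
#'
#' @param pfs,os [parametric_survival()] models fitted on the control arm
#'   (time in months).
#' @param hrs A [hazard_ratio_set()].
#' @param lt A life table (see [make_life_table()]).
#' @param strategy `"control"` or `"intervention"`.
#' @param n_cycles Number of cycles to tabulate.
#' @param start_age Cohort age at cycle 0.
#' @param cycle_days Cycle length in days.
#' @param male_fraction Cohort male fraction for the life-table weighting.
#' @param per_cycle_max Apply the background mortality as a cyclewise maximum
#'   instead of a permanent switch (scenario flag).
#' @return A [transition_schedule()].
#' @export
derive_transitions <- function(pfs, os, hrs, lt, strategy, n_cycles,
                               start_age = 63, cycle_days = 28,
                               male_fraction = 0.5, per_cycle_max = FALSE) {
  strategy <- match.arg(strategy, c("control", "intervention"))
  p_pfs <- cycle_probability(pfs, seq_len(n_cycles) - 1, cycle_days)
  p_os <- cycle_probability(os, seq_len(n_cycles) - 1, cycle_days)
  if (strategy == "intervention") {
    p_pfs <- apply_hazard_ratio(pmin(p_pfs, 1 - 1e-12), hrs$hr_pfs)
    p_os <- apply_hazard_ratio(pmin(p_os, 1 - 1e-12), hrs$hr_os)
  }
  p_bg <- background_mortality(lt, start_age, n_cycles, cycle_days,
                               male_fraction)
  p_sd_pd <- p_sd_d <- p_pd_d <- numeric(n_cycles)
  occ <- c(sd = 1, pd = 0)
  k_cross <- .override_cycle(p_os, p_bg)
  cross_at <- if (is.null(k_cross)) NULL else k_cross - 1L
  for (i in seq_len(n_cycles)) {
    alive <- occ[["sd"]] + occ[["pd"]]
    w_sd <- if (alive > 0) occ[["sd"]] / alive else 1
    use_bg <- if (per_cycle_max) p_bg[i] > p_os[i]
    else !is.null(k_cross) && i >= k_cross
    if (use_bg) {
      p_d <- min(p_bg[i], 1)
      p_sd_d[i] <- p_d
      p_pd_d[i] <- p_d
    } else {
      sp <- split_death_probability(min(p_os[i], 1 - 1e-12), unname(w_sd),
                                    hrs$hr_sd_vs_pd)
      p_sd_d[i] <- sp$p_sd
      p_pd_d[i] <- sp$p_pd
    }
    p_sd_pd[i] <- max(0, min(p_pfs[i] - p_sd_d[i], 1 - p_sd_d[i]))
    occ <- c(sd = occ[["sd"]] * (1 - p_sd_pd[i] - p_sd_d[i]),
             pd = occ[["pd"]] * (1 - p_pd_d[i]) + occ[["sd"]] * p_sd_pd[i])
  }
  transition_schedule(p_sd_pd, p_sd_d, p_pd_d, strategy, cycle_days,
                      override_cycle = cross_at)
}

#' Build a transition schedule from the case-study probability table
#'
#' Uses the printed per-cycle transition probabilities of the case study
#' directly: the SD-to-PD probability is constant over time (exponential time
#' profile), while the two death probabilities follow the shape of a fitted
#' gamma overall-survival hazard, rescaled on the cumulative-hazard scale so
#' that the cycle-0 value matches the printed probability. Background
#' mortality from the life table overrides each death probability permanently
#' from its first crossing.
#'
#' @param fixture A [case_study_fixture()] (or a compatible list carrying
#'   `transitions`, `os_profile`, and cohort fields).
#' @param strategy `"control"` or `"intervention"`.
#' @param n_cycles Number of cycles to tabulate.
#' @param lt Life table; defaults to the fixture's bundled synthetic table.
#' @param per_cycle_max Cyclewise-maximum override (scenario flag).
#' @param pfs_stop_month If finite, disease progression (SD to PD) is switched
#'   off from this time (months) on — used by the no-extrapolation scenario.
#' @return A [transition_schedule()].
#' @export
schedule_from_table <- function(fixture, strategy, n_cycles,
                                lt = NULL, per_cycle_max = FALSE,
                                pfs_stop_month = Inf) {
  strategy <- match.arg(strategy, c("control", "intervention"))
  tr <- fixture$transitions[[strategy]]
  if (is.null(tr) || anyNA(unlist(tr)))
    stop("fixture is missing transition probabilities for strategy '",
         strategy, "'")
  if (is.null(lt)) lt <- fixture$life_table
  cd <- fixture$cycle_days
  prof <- parametric_survival("gamma",
                              c(shape = fixture$os_profile$shape,
                                rate = fixture$os_profile$rate))
  # cumulative-hazard increments of the gamma profile, per cycle
  dh <- -log(1 - cycle_probability(prof, seq_len(n_cycles) - 1, cd))
  scale_to <- function(q0) 1 - exp(-dh * (-log(1 - q0) / dh[1]))
  p_sd_d <- scale_to(tr$sd_d)
  p_pd_d <- scale_to(tr$pd_d)
  p_bg <- background_mortality(lt, fixture$start_age, n_cycles, cd,
                               fixture$male_fraction[[strategy]])
  o_sd <- .override_mortality(p_sd_d, p_bg, per_cycle_max)
  o_pd <- .override_mortality(p_pd_d, p_bg, per_cycle_max)
  p_sd_d <- pmin(o_sd$p, 1)
  p_pd_d <- pmin(o_pd$p, 1)
  # the tabulated SD exit probability is the PFS-event probability
  # (progression or death); the SD-to-PD transition is the part not
  # explained by death in SD
  p_sd_pd <- pmax(0, pmin(tr$sd_pd - p_sd_d, 1 - p_sd_d))
  t_mid <- (seq_len(n_cycles) - 1) * cd / DAYS_PER_MONTH
  p_sd_pd[t_mid >= pfs_stop_month] <- 0
  transition_schedule(p_sd_pd, p_sd_d, p_pd_d, strategy, cd,
                      override_cycle = o_sd$cross)
}

#' Export a transition schedule for audit
#'
#' @param schedule A [transition_schedule()].
#' @param file Output CSV path (columns `cycle,p_sd_pd,p_sd_d,p_pd_d`).
#' @return The exported data.frame, invisibly.
#' @export
write_schedule <- function(schedule, file) {
  d <- data.frame(cycle = seq_len(schedule$n_cycles) - 1L,
                  p_sd_pd = schedule$p_sd_pd,
                  p_sd_d = schedule$p_sd_d,
                  p_pd_d = schedule$p_pd_d)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}
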