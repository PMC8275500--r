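#' Generate a synthetic national life table
#'
#' Produces an age/sex life table with Gompertz mortality (hazard doubling at
#' a fixed age interval), emulating the structure of national statistics
#' tables: one row per age and sex with the annual probability of death. The
#' annual probability reaches 1 at `max_age` as a closure guard.
#'
#' @param max_age Final age (years); `q(max_age) = 1`.
#' @param min_age First tabulated age.
#' @param hazard_at_min Named vector `c(male = , female = )`: annual mortality
#'   hazard at `min_age`.
#' @param doubling_time Years over which the hazard doubles.
#' @return A `life_table`: data.frame with columns `age`, `sex`,
#'   `annual_mortality`.
#' @export
#' @examples
#' lt <- make_life_table()
#' head(lt)
make_life_table <- function(max_age = 110, min_age = 50,
                            hazard_at_min = c(male = 0.0039, female = 0.0026),
                            doubling_time = 8) {
  if (max_age <= 63) stop("max_age must exceed 63")
  b <- log(2) / doubling_time
  ages <- min_age:max_age
  rows <- lapply(c("male", "female"), function(sx) {
    h <- hazard_at_min[[sx]] * exp(b * (ages - min_age))
    q <- 1 - exp(-h)
    q[ages == max_age] <- 1
    data.frame(age = ages, sex = sx, annual_mortality = pmin(q, 1))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read a life table from CSV (`age,sex,annual_mortality`)
#'
#' @param file CSV path.
#' @return A `life_table` data.frame.
#' @export
read_life_table <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("age", "sex", "annual_mortality") %in% names(d)))
    stop("life table must have columns age,sex,annual_mortality")
  if (any(d$annual_mortality < 0 | d$annual_mortality > 1))
    stop("annual mortality probabilities must lie in [0, 1]")
  for (sx in unique(d$sex)) {
    a <- sort(d$age[d$sex == sx])
    if (any(diff(a) != 1))
      stop("life-table ages must be contiguous within sex '", sx, "'")
  }
  class(d) <- c("life_table", "data.frame")
  d
}

#' Sex-mix weighted per-cycle background mortality
#'
#' Converts the annual mortality of a cohort of a given starting age into a
#' per-cycle probability series, weighting the male and female rates by the
#' cohort's male fraction: `q_cycle = 1 - (1 - q_annual)^(cycle_days/365.25)`.
#'
#' @param lt A life table.
#' @param start_age Cohort age at cycle 0 (years).
#' @param n_cycles Number of cycles.
#' @param cycle_days Cycle length in days.
#' @param male_fraction Proportion of the cohort that is male.
#' @return Numeric vector of length `n_cycles`: per-cycle death probability.
#' @export
background_mortality <- function(lt, start_age, n_cycles, cycle_days = 28,
                                 male_fraction = 0.5) {
  ages <- floor(start_age + (seq_len(n_cycles) - 1) * cycle_days / DAYS_PER_YEAR)
  top <- max(lt$age)
  if (min(ages) < min(lt$age))
    stop("life table does not cover age ", min(ages))
  ages <- pmin(ages, top)  # beyond the table the closing q = 1 row applies
  qm <- lt$annual_mortality[lt$sex == "male"][match(ages, lt$age[lt$sex == "male"])]
  qf <- lt$annual_mortality[lt$sex == "female"][match(ages, lt$age[lt$sex == "female"])]
  if (anyNA(qm) || anyNA(qf))
    stop("life table does not cover the required age span (",
         min(ages), "-", max(ages), ")")
  qa <- male_fraction * qm + (1 - male_fraction) * qf
  1 - (1 - qa)^(cycle_days / DAYS_PER_YEAR)
}
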