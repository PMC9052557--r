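#' VA-adjusted annual death probability
#'
#' Applies a relative-risk multiplier on the hazard scale:
#' q' = 1 - (1 - q)^rr. With rr = 1 the base probability is returned.
#'
#' @param base_prob Annual death probability in [0,1].
#' @param rr Relative risk (> 0); may be a vector (one per VA state).
#' @return Adjusted probability/ies.
#' @export
adjusted_death_probability <- function(base_prob, rr) {
  if (any(base_prob < 0) || any(base_prob > 1))
    stop("base_prob must lie in [0,1]", call. = FALSE)
  if (any(rr <= 0)) stop("rr must be > 0", call. = FALSE)
  1 - (1 - base_prob)^rr
}

#' Cohort annual death probability from a sex-specific life table
#'
#' Weighted average of the male and female death probabilities at the
#' cohort's current mean age, with linear interpolation between integer
#' ages and weights given by the female share.
#'
#' @param age Cohort mean age (within the table's range).
#' @param pct_female Female share in [0,1].
#' @param life_table A `namd_life_table`.
#' @return Annual death probability.
#' @export
cohort_death_probability <- function(age, pct_female, life_table) {
  amin <- min(life_table$age); amax <- max(life_table$age)
  if (age < amin || age > amax)
    stop(sprintf("age %.1f outside life-table range [%d, %d]",
                 age, amin, amax), call. = FALSE)
  q_m <- stats::approx(life_table$age, life_table$male, xout = age)$y
  q_f <- stats::approx(life_table$age, life_table$female, xout = age)$y
  pct_female * q_f + (1 - pct_female) * q_m
}

#' Update the bilateral-disease fraction for one cycle
#'
#' Unilateral patients convert to bilateral disease with a constant annual
#' probability; bilateral status is absorbing.
#'
#' @param b_t Bilateral fraction among alive patients at cycle t.
#' @param annual_second_eye_prob Annual second-eye incidence in [0,1].
#' @return Bilateral fraction at cycle t+1.
#' @export
#' @examples
#' update_bilateral_fraction(0.2714, 0.166) # 0.39234...
update_bilateral_fraction <- function(b_t, annual_second_eye_prob) {
  b_t + (1 - b_t) * annual_second_eye_prob
}

#' Simulate the cohort trace for one strategy
#'
#' Runs the annual-cycle cohort simulation: cycle 0 places the on-treatment
#' cohort on the baseline BCVA distribution at the baseline mean age with
#' the baseline bilateral fraction. Each subsequent cycle applies, in order:
#' (1) state-specific mortality (life-table probability at the current age,
#' adjusted by the per-state relative risks), (2) VA-state transitions of the
#' surviving on-treatment mass (Year-1 matrix in cycle 1, Year-2+ matrix
#' thereafter), (3) treatment discontinuation (off-treatment mass retains its
#' VA state and no longer transitions), (4) bilateral-disease accrual, and
#' (5) one year of ageing.
#'
#' @param strategy Strategy name.
#' @param p A validated `namd_params` object.
#' @param matrices List with `year1` and `year2plus` matrices; defaults to
#'   [strategy_matrices()] of `p`.
#' @param life_table A `namd_life_table`.
#' @return A `namd_trace`: data.frame with one row per cycle 0..horizon and
#'   columns `cycle`, `age`, `on_<state>` x6, `off_<state>` x6, `on`, `off`,
#'   `alive`, `dead`, `bilateral`.
#' @export
run_cohort <- function(strategy, p, matrices = strategy_matrices(p, strategy),
                       life_table = generate_life_table()) {
  s <- p$settings
  horizon <- s$horizon
  if (s$mean_age + horizon > max(life_table$age))
    stop("horizon exceeds life-table age range", call. = FALSE)

  on  <- p$baseline_distribution
  off <- stats::setNames(rep(0, n_va_states), va_states)
  dead <- 0
  b <- s$bilateral_baseline
  age <- s$mean_age

  rows <- vector("list", horizon + 1)
  snap <- function(t) {
    data.frame(cycle = t, age = age,
               t(stats::setNames(on, paste0("on_", va_states))),
               t(stats::setNames(off, paste0("off_", va_states))),
               on = sum(on), off = sum(off), alive = sum(on) + sum(off),
               dead = dead, bilateral = b, check.names = FALSE)
  }
  rows[[1]] <- snap(0)

  for (t in seq_len(horizon)) {
    q_base <- cohort_death_probability(age, s$pct_female, life_table)
    q_state <- adjusted_death_probability(q_base, s$mortality_rr)
    died <- sum(on * q_state) + sum(off * q_state)
    on  <- on  * (1 - q_state)
    off <- off * (1 - q_state)
    dead <- dead + died

    m <- if (t == 1) matrices$year1 else matrices$year2plus
    on <- as.numeric(on %*% m)
    names(on) <- va_states

    d <- s$discontinuation_annual_prob
    if (d > 0) {
      off <- off + on * d
      on <- on * (1 - d)
    }

    b <- update_bilateral_fraction(b, s$second_eye_annual_prob)
    age <- age + 1
    rows[[t + 1]] <- snap(t)
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  attr(trace, "strategy") <- strategy
  class(trace) <- c("namd_trace", "data.frame")
  trace
}

#' Export a cohort trace as CSV
#' @param trace A `namd_trace`.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(trace)
}
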