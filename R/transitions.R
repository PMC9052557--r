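#' Rescale a partial-year BCVA change to a full year
#'
#' Year-2 trial efficacy covers weeks 53-96 (44 weeks). Assuming visual
#' acuity continues to change at the same rate for the remaining weeks, the
#' mean change is extrapolated linearly to the target period.
#'
#' @param mean_change Mean BCVA change in ETDRS letters over `observed_weeks`.
#' @param observed_weeks Weeks the observation covers (> 0).
#' @param target_weeks Weeks to rescale to (default 52, one model cycle).
#' @return Rescaled mean change in letters.
#' @export
#' @examples
#' scale_partial_year_change(-0.61, 44) # -0.7209...
scale_partial_year_change <- function(mean_change, observed_weeks,
                                      target_weeks = 52) {
  if (any(observed_weeks <= 0) || any(target_weeks <= 0))
    stop("weeks must be positive", call. = FALSE)
  mean_change * target_weeks / observed_weeks
}

#' Probabilities of gaining/losing one or two VA states
#'
#' The annual BCVA letter change is modelled as Normal(mean, sd). Crossing
#' +/-7.5 letters corresponds to moving one 15-letter state, crossing
#' +/-22.5 letters to moving two; movement beyond two states is not allowed,
#' so the tails accumulate in the two-state bands.
#'
#' @param mean Mean letter change.
#' @param sd Standard deviation of the letter change (> 0).
#' @param cutoffs Named vector as returned by [letter_cutoffs()].
#' @return Named numeric vector `(gain2, gain1, stay, lose1, lose2)`
#'   summing to 1.
#' @export
#' @examples
#' band_probabilities(6.50, 13.35)
band_probabilities <- function(mean, sd, cutoffs = letter_cutoffs()) {
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  c1 <- cutoffs[["one_state"]]
  c2 <- cutoffs[["two_state"]]
  if (!(0 < c1 && c1 < c2))
    stop("cutoffs must satisfy 0 < one_state < two_state", call. = FALSE)
  z <- function(x) stats::pnorm((x - mean) / sd)
  c(gain2 = 1 - z(c2),
    gain1 = z(c2) - z(c1),
    stay  = z(c1) - z(-c1),
    lose1 = z(-c1) - z(-c2),
    lose2 = z(-c2))
}

#' Build a six-state annual transition matrix from band probabilities
#'
#' Row `i` receives `gain2` at `i-2`, `gain1` at `i-1`, `stay` at `i`,
#' `lose1` at `i+1` and `lose2` at `i+2`; probability mass that would
#' overshoot the best or worst state accumulates in the boundary state, so
#' every row sums to 1 exactly.
#'
#' @param bands Output of [band_probabilities()] (or any 5-vector in that
#'   order summing to 1).
#' @return A 6x6 row-stochastic matrix with VA-state dimnames.
#' @export
build_transition_matrix <- function(bands) {
  if (length(bands) != 5 || any(bands < 0) || abs(sum(bands) - 1) > 1e-9)
    stop("bands must be 5 non-negative probabilities summing to 1",
         call. = FALSE)
  m <- matrix(0, n_va_states, n_va_states,
              dimnames = list(from = va_states, to = va_states))
  moves <- c(-2L, -1L, 0L, 1L, 2L) # in ordinal index; negative = improve
  for (i in seq_len(n_va_states)) {
    for (k in seq_along(moves)) {
      j <- min(max(i + moves[k], 1L), n_va_states)
      m[i, j] <- m[i, j] + bands[[k]]
    }
  }
  m
}

#' Annual transition matrices for one strategy
#'
#' Builds the Year-1 and Year-2+ matrices from a parameter set. The Year-2
#' mean change, observed over 44 weeks, is rescaled to 52 weeks; the SD is
#' kept at its reported value unless `settings$scale_year2_sd` is TRUE, in
#' which case it is scaled by sqrt(52/observed_weeks).
#'
#' @param p A `namd_params` object.
#' @param strategy Strategy name.
#' @return List with elements `year1` and `year2plus`, each a 6x6 matrix.
#' @export
strategy_matrices <- function(p, strategy) {
  eff <- p$efficacy[[strategy]]
  if (is.null(eff)) stop("unknown strategy: ", strategy, call. = FALSE)
  build_one <- function(e) {
    m <- scale_partial_year_change(e$mean, e$observed_weeks, 52)
    s <- if (isTRUE(p$settings$scale_year2_sd))
      e$sd * sqrt(52 / e$observed_weeks) else e$sd
    build_transition_matrix(band_probabilities(m, s))
  }
  list(year1 = build_one(eff$year1), year2plus = build_one(eff$year2plus))
}

#' Annualize an adverse-event incidence observed over a trial period
#'
#' Converts an event proportion observed over `observed_weeks` (96 weeks in
#' the pivotal trials) to an annual incidence by linear time scaling:
#' (count / n) * 52 / observed_weeks.
#'
#' @param count Number of patients with the event (vectorized).
#' @param n_patients Arm size.
#' @param observed_weeks Observation period in weeks.
#' @return Annual incidence proportion(s).
#' @export
#' @examples
#' annualize_incidence(4, 730) # 0.00297 -> prints as 0.30%
annualize_incidence <- function(count, n_patients, observed_weeks = 96) {
  if (any(observed_weeks <= 0)) stop("observed_weeks must be > 0", call. = FALSE)
  if (any(n_patients <= 0)) stop("n_patients must be > 0", call. = FALSE)
  if (any(count < 0) || any(count > n_patients))
    stop("count must lie in [0, n_patients]", call. = FALSE)
  (count / n_patients) * 52 / observed_weeks
}

#' Export a transition matrix as CSV
#' @param m A 6x6 transition matrix.
#' @param path Output file.
#' @export
write_transition_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(m)
}
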