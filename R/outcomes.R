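#' Discount factor for an annual cycle
#'
#' @param year Cycle index (cycle 1 outcomes are discounted one year).
#' @param rate Annual discount rate (>= 0); 0.03 in the base case.
#' @return (1 + rate)^(-year).
#' @export
discount_factor <- function(year, rate) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (any(year < 0)) stop("year must be >= 0", call. = FALSE)
  (1 + rate)^(-year)
}

#' Annual QALY loss from injection discomfort
#'
#' Each intravitreal injection is assumed to cause complete utility loss for
#' `days` days in a fraction `fraction` of patients (defaults: 1 day, 50%),
#' i.e. n * 0.5 / 365.25 QALYs per treated patient-year at the defaults.
#'
#' @param n_injections Injections per year.
#' @param fraction Fraction of patients affected.
#' @param days Days of full utility loss per injection.
#' @return QALY loss per on-treatment patient-year.
#' @export
#' @examples
#' annual_injection_disutility(6.66) # 0.00912
annual_injection_disutility <- function(n_injections, fraction = 0.5,
                                        days = 1) {
  if (any(n_injections < 0)) stop("n_injections must be >= 0", call. = FALSE)
  n_injections * fraction * days / 365.25
}

#' Expected duration (years) of an adverse-event disutility
#' @param duration List with `years` and `weights` (mixture over durations).
#' @return Expected duration in years.
#' @export
ae_expected_duration <- function(duration) {
  sum(duration$years * duration$weights)
}

#' Annual QALY loss from treatment-related adverse events
#'
#' Sum over events of annual incidence x disutility x expected duration
#' (in years). Events with zero disutility contribute nothing.
#'
#' @param incidence Named annual incidences (proportion/year).
#' @param disutility Named utility decrements (positive values).
#' @param duration Named list of duration mixtures (`years`, `weights`).
#' @return QALY loss per on-treatment patient-year.
#' @export
#' @examples
#' annual_ae_disutility(c(endophthalmitis = 0.0030),
#'                      c(endophthalmitis = 0.3),
#'                      list(endophthalmitis = list(years = c(1, 0.125),
#'                                                  weights = c(0.2, 0.8))))
annual_ae_disutility <- function(incidence, disutility, duration) {
  if (length(incidence) == 0) return(0)
  ev <- names(incidence)
  sum(vapply(ev, function(e)
    incidence[[e]] * disutility[[e]] * ae_expected_duration(duration[[e]]),
    numeric(1)))
}

# per-strategy AE disutility per on-treatment patient-year
strategy_ae_disutility <- function(p, strategy) {
  ae <- p$adverse_events
  annual_ae_disutility(ae$incidence[[strategy]], ae$disutility, ae$duration)
}

# injections/year for a given cycle's period label
injections_for_period <- function(p, strategy, period) {
  p$injections[[strategy]][[period]]
}

# map cycle index to injection-schedule period
cycle_period <- function(t) {
  if (t <= 1) "year1" else if (t == 2) "year2" else "subsequent"
}

#' Undiscounted QALYs accrued in one cycle
#'
#' State utilities weighted by occupancy (on- and off-treatment mass both
#' carry their VA-state utility), minus injection and adverse-event
#' disutilities on the on-treatment mass, minus the optional bilateral
#' utility decrement on the alive bilateral fraction.
#'
#' @param trace_row One row of a `namd_trace`.
#' @param p Parameter set.
#' @param strategy Strategy name.
#' @param period One of "year1", "year2", "subsequent".
#' @return List with `total` and components `state_utility`,
#'   `injection_disutility`, `ae_disutility`, `bilateral_decrement`.
#' @export
cycle_qalys <- function(trace_row, p, strategy, period) {
  occ <- as.numeric(trace_row[paste0("on_", va_states)]) +
    as.numeric(trace_row[paste0("off_", va_states)])
  su <- sum(occ * p$utilities)
  on_mass <- trace_row[["on"]]
  inj <- annual_injection_disutility(
    injections_for_period(p, strategy, period),
    p$settings$injection_disutility_fraction,
    p$settings$injection_disutility_days) * on_mass
  aed <- strategy_ae_disutility(p, strategy) * on_mass
  bil <- trace_row[["alive"]] * trace_row[["bilateral"]] *
    p$settings$bilateral_utility_decrement
  list(total = su - inj - aed - bil, state_utility = su,
       injection_disutility = inj, ae_disutility = aed,
       bilateral_decrement = bil)
}

#' Undiscounted per-category costs accrued in one cycle
#'
#' Acquisition and administration costs scale with the period's injection
#' frequency, the on-treatment mass, and the bilateral treatment factor
#' (1 + bilateral_cost_factor x bilateral fraction: treating the fellow eye
#' doubles drug and administration use for that fraction). Monitoring (OCT)
#' accrues to all alive patients once yearly; AE management to on-treatment
#' mass; blindness and low-vision costs to the occupancy of the mapped
#' states, using direct costs under the NHS perspective and total
#' (direct + indirect) costs under the societal perspective.
#'
#' @inheritParams cycle_qalys
#' @param perspective "nhs" or "societal".
#' @return Named numeric vector: acquisition, administration, monitoring,
#'   ae_management, blindness, low_vision, total.
#' @export
cycle_costs <- function(trace_row, p, strategy, period,
                        perspective = p$settings$perspective) {
  if (!perspective %in% c("nhs", "societal"))
    stop("unknown perspective: ", perspective, call. = FALSE)
  co <- p$costs
  on_mass <- trace_row[["on"]]
  alive <- trace_row[["alive"]]
  b <- trace_row[["bilateral"]]
  eyes <- 1 + p$settings$bilateral_cost_factor * b
  n_inj <- injections_for_period(p, strategy, period)

  acq <- co$vial_price[[strategy]] * n_inj * on_mass * eyes
  adm <- co$administration * n_inj * on_mass * eyes
  mon <- co$oct_unit * co$oct_per_year * alive
  inc <- p$adverse_events$incidence[[strategy]]
  aem <- sum(inc * co$ae_unit[names(inc)]) * on_mass

  occ_of <- function(state)
    trace_row[[paste0("on_", state)]] + trace_row[[paste0("off_", state)]]
  if (perspective == "societal") {
    c_bl <- co$blindness_total; c_lv <- co$low_vision_total
  } else {
    c_bl <- co$blindness_direct; c_lv <- co$low_vision_direct
  }
  bl <- c_bl * occ_of(p$settings$blindness_state)
  lv <- c_lv * occ_of(p$settings$low_vision_state)

  out <- c(acquisition = acq, administration = adm, monitoring = mon,
           ae_management = aem, blindness = bl, low_vision = lv)
  c(out, total = sum(out))
}

#' Aggregate a cohort trace into discounted outcomes and costs
#'
#' Cycle t (t = 1..horizon) contributes one year of exposure valued at the
#' end-of-cycle state occupancy (or, with the half-cycle correction enabled,
#' the average of the start- and end-of-cycle occupancies), discounted at
#' (1+r)^-t.
#'
#' @param trace A `namd_trace`.
#' @param p Parameter set.
#' @param strategy Strategy name; defaults to the trace's strategy.
#' @param perspective "nhs" or "societal".
#' @return List with `outcomes` (ly, qaly, and QALY components) and `costs`
#'   (discounted euros per category plus total), plus `undiscounted` totals.
#' @export
aggregate_results <- function(trace, p,
                              strategy = attr(trace, "strategy"),
                              perspective = p$settings$perspective) {
  s <- p$settings
  horizon <- max(trace$cycle)
  hcc <- isTRUE(s$half_cycle_correction)

  comp <- c("state_utility", "injection_disutility", "ae_disutility",
            "bilateral_decrement")
  out <- c(ly = 0, qaly = 0,
           stats::setNames(rep(0, length(comp)), comp))
  out_undisc <- c(ly = 0, qaly = 0)
  cost_cat <- c("acquisition", "administration", "monitoring",
                "ae_management", "blindness", "low_vision", "total")
  costs <- stats::setNames(rep(0, length(cost_cat)), cost_cat)
  costs_undisc <- costs

  avg_row <- function(r0, r1) {
    num <- vapply(names(r1), function(nm) is.numeric(r1[[nm]]), logical(1))
    r <- r1
    r[num] <- (as.numeric(r0[num]) + as.numeric(r1[num])) / 2
    r
  }

  for (t in seq_len(horizon)) {
    row <- trace[trace$cycle == t, ]
    if (hcc) row <- avg_row(trace[trace$cycle == t - 1, ], row)
    per <- cycle_period(t)
    df <- discount_factor(t, s$discount_rate)

    q <- cycle_qalys(row, p, strategy, per)
    cc <- cycle_costs(row, p, strategy, per, perspective)

    out["ly"] <- out["ly"] + row[["alive"]] * df
    out["qaly"] <- out["qaly"] + q$total * df
    for (nm in comp) out[nm] <- out[nm] + q[[nm]] * df
    out_undisc["ly"] <- out_undisc["ly"] + row[["alive"]]
    out_undisc["qaly"] <- out_undisc["qaly"] + q$total
    costs <- costs + cc * df
    costs_undisc <- costs_undisc + cc
  }
  list(outcomes = as.list(out), costs = as.list(costs),
       undiscounted = list(outcomes = as.list(out_undisc),
                           costs = as.list(costs_undisc)),
       strategy = strategy, perspective = perspective, horizon = horizon)
}
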