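#' Gompertz-Makeham parameters for the synthetic life table
#'
#' Stand-in for the Italian 2018 (ISTAT) sex-specific period life tables,
#' which are not shipped with the package. The annual death probability at
#' integer age a is q(a) = 1 - exp(-(A + B * c^a)). Defaults were calibrated
#' once so that remaining life expectancy at age 75 is ~13.2 years (female)
#' and ~11.0 years (male), matching the Italian 2018 ballpark; they are not
#' the official tables. Use [read_life_table()] with the real qx values for
#' reproduction runs.
#'
#' @param sex `"female"` or `"male"`.
#' @return List with elements `makeham` (A), `scale` (B), `shape` (c), `sex`.
#' @export
gompertz_makeham_params <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female")
    list(makeham = 5e-4, scale = 4.45e-6, shape = 1.12, sex = "female")
  else
    list(makeham = 5e-4, scale = 6.42e-6, shape = 1.12, sex = "male")
}

#' Generate a synthetic life table
#'
#' @param female,male Gompertz-Makeham parameter lists
#'   (see [gompertz_makeham_params()]).
#' @param max_age Terminal age; q is forced to 1 there.
#' @return A `namd_life_table`: data.frame with columns `age`, `male`,
#'   `female` holding annual death probabilities qx.
#' @export
#' @examples
#' lt <- generate_life_table()
#' head(lt)
generate_life_table <- function(female = gompertz_makeham_params("female"),
                                male = gompertz_makeham_params("male"),
                                max_age = 120) {
  gm_q <- function(par, ages) {
    if (par$makeham < 0 || par$scale <= 0 || par$shape <= 0)
      stop("invalid Gompertz-Makeham parameters", call. = FALSE)
    q <- 1 - exp(-(par$makeham + par$scale * par$shape^ages))
    if (any(q <= 0) || any(q > 1))
      stop("parameters imply death probabilities outside (0,1]", call. = FALSE)
    q
  }
  ages <- 0:max_age
  lt <- data.frame(age = ages,
                   male = gm_q(male, ages),
                   female = gm_q(female, ages))
  lt$male[lt$age == max_age] <- 1
  lt$female[lt$age == max_age] <- 1
  class(lt) <- c("namd_life_table", "data.frame")
  lt
}

#' Write / read a life table as a long-format CSV (age, sex, qx)
#' @param lt A `namd_life_table`.
#' @param path CSV file path.
#' @export
write_life_table <- function(lt, path) {
  long <- rbind(data.frame(age = lt$age, sex = "male", qx = lt$male),
                data.frame(age = lt$age, sex = "female", qx = lt$female))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}

#' @rdname write_life_table
#' @return `read_life_table` returns a `namd_life_table`.
#' @export
read_life_table <- function(path) {
  long <- utils::read.csv(path)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(long)))
    stop("life table CSV must have columns age, sex, qx", call. = FALSE)
  wide <- merge(long[long$sex == "male", c("age", "qx")],
                long[long$sex == "female", c("age", "qx")],
                by = "age", suffixes = c("_m", "_f"))
  wide <- wide[order(wide$age), ]
  lt <- data.frame(age = wide$age, male = wide$qx_m, female = wide$qx_f)
  if (any(lt$male < 0 | lt$male > 1 | lt$female < 0 | lt$female > 1))
    stop("qx values must lie in [0,1]", call. = FALSE)
  class(lt) <- c("namd_life_table", "data.frame")
  lt
}

#' Synthetic stand-in baseline BCVA distribution
#'
#' WARNING: synthetic. The trial baseline distribution by 15-letter band is
#' published only as a figure and is not reproduced here. This stand-in
#' places most patients in the middle bands (56-70 and 41-55 letters),
#' consistent with typical nAMD trial entry criteria (baseline BCVA roughly
#' 60 +/- 13 letters). Override `baseline_distribution` in the configuration
#' with the trial values for reproduction runs.
#'
#' @return Named numeric vector over the six VA states, summing to 1.
#' @export
default_baseline_distribution <- function() {
  stats::setNames(c(0.03, 0.22, 0.38, 0.27, 0.085, 0.015), va_states)
}

#' Simulate individual-level annual BCVA letter changes
#'
#' Monte-Carlo oracle for the parametric (normal-CDF) transition estimator:
#' draws per-patient letter changes from Normal(mean, sd).
#'
#' @param n Number of individuals.
#' @param mean,sd Letter-change distribution parameters (sd > 0).
#' @param seed Integer seed; the draw is reproducible from it.
#' @return Object of class `namd_sim_cohort`: list with `changes` (numeric
#'   vector), `mean`, `sd`, `seed`.
#' @export
simulate_individual_changes <- function(n, mean, sd, seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list(changes = stats::rnorm(n, mean, sd), mean = mean, sd = sd,
              seed = seed)
  class(out) <- "namd_sim_cohort"
  out
}

#' Simulate a cohort with baseline states and letter scores
#'
#' Assigns each individual a baseline VA state from `baseline_dist`, a
#' continuous letter score uniform within the state's 15-letter band
#' (clamped to [0, 100]), and an annual letter change.
#'
#' @inheritParams simulate_individual_changes
#' @param baseline_dist Named occupancy vector over the six states.
#' @return `namd_sim_cohort` with additional fields `state0` (ordinal index,
#'   1 = best) and `letters0`.
#' @export
simulate_cohort <- function(n, mean, sd, seed,
                            baseline_dist = default_baseline_distribution()) {
  sim <- simulate_individual_changes(n, mean, sd, seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  st <- sample.int(n_va_states, n, replace = TRUE, prob = baseline_dist)
  lo <- c(86, 71, 56, 41, 26, 0)[st]
  hi <- c(100, 85, 70, 55, 40, 25)[st]
  sim$state0 <- st
  sim$letters0 <- pmin(pmax(stats::runif(n, lo, hi), 0), 100)
  sim
}

#' Empirical transition matrix from simulated letter changes
#'
#' Classifies each simulated change into the five movement bands using the
#' one- and two-state letter cutoffs (with the two-state movement cap) and
#' assembles the empirical band frequencies into a 6x6 matrix with boundary
#' accumulation, exactly as [build_transition_matrix()] does for the
#' parametric bands.
#'
#' @param cohort A `namd_sim_cohort`, or a numeric vector of letter changes.
#' @param cutoffs Named vector as returned by [letter_cutoffs()].
#' @return 6x6 row-stochastic matrix of empirical frequencies.
#' @export
empirical_transition_matrix <- function(cohort, cutoffs = letter_cutoffs()) {
  x <- if (is.list(cohort)) cohort$changes else cohort
  c1 <- cutoffs[["one_state"]]
  c2 <- cutoffs[["two_state"]]
  bands <- c(
    gain2 = mean(x >= c2),
    gain1 = mean(x >= c1 & x < c2),
    stay  = mean(x > -c1 & x < c1),
    lose1 = mean(x > -c2 & x <= -c1),
    lose2 = mean(x <= -c2)
  )
  build_transition_matrix(bands / sum(bands))
}
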