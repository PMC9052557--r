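#' Registry of uncertain parameters
#'
#' Enumerates every model input varied in sensitivity analysis, with its
#' sampling family (normal for utilities and efficacy means, beta for
#' probabilities and incidences, gamma for costs and resource-use counts),
#' mean, standard error and domain bounds. Where the source reports no
#' standard error, SE is set to 10% of the mean and flagged `assumed10`;
#' deterministic bounds for those parameters are +/-10% rather than a 95%
#' CI. Efficacy means use the SE of a mean, SD/sqrt(n). Annual injection
#' counts exceed 1 and are therefore sampled from gamma rather than beta.
#'
#' @param p A `namd_params` object.
#' @return Data.frame with columns `name`, `family`, `mean`, `se`,
#'   `se_source`, `lower`, `upper`, and attribute `paths` (list of index
#'   paths into the parameter tree).
#' @export
uncertain_parameters <- function(p) {
  rows <- list(); paths <- list()
  add <- function(name, path, family, mean, se, se_source,
                  lower = -Inf, upper = Inf) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, family = family, mean = mean, se = se,
      se_source = se_source, lower = lower, upper = upper)
    paths[[length(paths) + 1]] <<- path
  }
  for (st in strategies(p)) {
    for (per in names(p$efficacy[[st]])) {
      e <- p$efficacy[[st]][[per]]
      add(sprintf("efficacy.%s.%s.mean", st, per),
          c("efficacy", st, per, "mean"),
          "normal", e$mean, e$sd / sqrt(e$n), "reported")
    }
    for (per in names(p$injections[[st]]))
      add(sprintf("injections.%s.%s", st, per),
          c("injections", st, per),
          "gamma", p$injections[[st]][[per]],
          0.10 * p$injections[[st]][[per]], "assumed10", lower = 0)
    add(sprintf("costs.vial_price.%s", st),
        c("costs", "vial_price", st),
        "gamma", p$costs$vial_price[[st]],
        0.10 * p$costs$vial_price[[st]], "assumed10", lower = 0)
  }
  for (nm in c("administration", "oct_unit", "blindness_direct",
               "low_vision_direct", "blindness_total", "low_vision_total"))
    add(sprintf("costs.%s", nm), c("costs", nm),
        "gamma", p$costs[[nm]], 0.10 * p$costs[[nm]], "assumed10", lower = 0)
  for (ev in p$adverse_events$events)
    add(sprintf("costs.ae_unit.%s", ev), c("costs", "ae_unit", ev),
        "gamma", p$costs$ae_unit[[ev]], 0.10 * p$costs$ae_unit[[ev]],
        "assumed10", lower = 0)
  for (stt in va_states)
    add(sprintf("utilities.%s", stt), c("utilities", stt),
        "normal", p$utilities[[stt]], 0.10 * p$utilities[[stt]],
        "assumed10", lower = 0, upper = 1)
  for (ev in p$adverse_events$events) {
    d <- p$adverse_events$disutility[[ev]]
    if (d > 0)
      add(sprintf("adverse_events.disutility.%s", ev),
          c("adverse_events", "disutility", ev),
          "normal", d, 0.10 * d, "assumed10", lower = 0, upper = 1)
  }
  for (st in strategies(p))
    for (ev in p$adverse_events$events)
      add(sprintf("adverse_events.incidence.%s.%s", st, ev),
          c("adverse_events", "incidence", st, ev),
          "beta", p$adverse_events$incidence[[st]][[ev]],
          p$adverse_events$incidence_se[[st]][[ev]], "reported",
          lower = 0, upper = 1)
  # baseline bilateral share has a binomial SE from 396/1459
  n1 <- 1459; pb <- p$settings$bilateral_baseline
  add("settings.bilateral_baseline", c("settings", "bilateral_baseline"),
      "beta", pb, sqrt(pb * (1 - pb) / n1), "reported", lower = 0, upper = 1)
  add("settings.second_eye_annual_prob",
      c("settings", "second_eye_annual_prob"),
      "beta", p$settings$second_eye_annual_prob,
      0.10 * p$settings$second_eye_annual_prob, "assumed10",
      lower = 0, upper = 1)
  add("settings.injection_disutility_fraction",
      c("settings", "injection_disutility_fraction"),
      "beta", p$settings$injection_disutility_fraction,
      0.10 * p$settings$injection_disutility_fraction, "assumed10",
      lower = 0, upper = 1)
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  attr(reg, "paths") <- paths
  reg
}

# assign a value into the parameter tree at a registry path
set_param_value <- function(p, path, value) {
  pl <- unclass(p)
  pl[[path]] <- value
  class(pl) <- "namd_params"
  pl
}

#' Deterministic sensitivity bounds for one parameter
#'
#' With a reported standard error, the bounds are the 95% confidence limits
#' mean +/- 1.96 SE, clipped to the parameter's domain; with no reported
#' uncertainty, mean x (1 -/+ 0.10). A zero SE collapses both bounds to the
#' mean.
#'
#' @param meta One row of [uncertain_parameters()] (data.frame or list with
#'   `mean`, `se`, `se_source`, `lower`, `upper`).
#' @return Numeric vector `c(low, high)`.
#' @export
dsa_bounds <- function(meta) {
  m <- meta$mean; se <- meta$se
  if (se == 0) return(c(low = m, high = m))
  if (identical(meta$se_source, "reported")) {
    lo <- m - 1.96 * se; hi <- m + 1.96 * se
  } else {
    lo <- m * 0.90; hi <- m * 1.10
  }
  lo <- min(max(lo, meta$lower), meta$upper)
  hi <- min(max(hi, meta$lower), meta$upper)
  c(low = lo, high = hi)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full pairwise comparison with each uncertain parameter set to
#' its lower and upper deterministic bound, everything else at base case.
#' Entries are sorted by descending ICER range.
#'
#' @param p A `namd_params` object.
#' @param life_table Life table used for every run.
#' @param top Number of entries to return (default 10; `Inf` for all).
#' @return Data.frame with columns `parameter`, `low`, `high`, `icer_base`,
#'   `icer_low`, `icer_high`, `range`, `label_low`, `label_high`.
#' @export
one_way_dsa <- function(p, life_table = generate_life_table(), top = 10) {
  reg <- uncertain_parameters(p)
  paths <- attr(reg, "paths")
  base <- run_comparison(p, life_table = life_table)
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    b <- dsa_bounds(reg[i, ])
    one <- function(v) {
      if (v == reg$mean[i]) return(base)
      run_comparison(set_param_value(p, paths[[i]], v),
                     life_table = life_table)
    }
    rl <- one(b[["low"]]); rh <- one(b[["high"]])
    data.frame(parameter = reg$name[i], low = b[["low"]], high = b[["high"]],
               icer_base = base$icer, icer_low = rl$icer, icer_high = rh$icer,
               range = abs(rh$icer - rl$icer),
               label_low = rl$label, label_high = rh$label)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  utils::head(out, top)
}

#' Method-of-moments beta shape parameters
#'
#' @param mean Mean in (0,1).
#' @param se Standard error (>= 0); `se = 0` flags a degenerate point mass.
#' @return List with `alpha`, `beta`, and `degenerate`.
#' @export
#' @examples
#' beta_from_moments(0.166, 0.0166)
beta_from_moments <- function(mean, se) {
  if (se == 0) return(list(alpha = NA_real_, beta = NA_real_,
                           degenerate = TRUE))
  if (mean <= 0 || mean >= 1)
    stop("beta mean must lie strictly in (0,1)", call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu <= 0)
    stop("infeasible beta moments: se^2 >= mean*(1-mean)", call. = FALSE)
  list(alpha = mean * nu, beta = (1 - mean) * nu, degenerate = FALSE)
}

#' Method-of-moments gamma shape and scale
#'
#' @param mean Mean (> 0).
#' @param se Standard error (>= 0); `se = 0` flags a degenerate point mass.
#' @return List with `shape`, `scale`, and `degenerate`.
#' @export
#' @examples
#' gamma_from_moments(680, 68) # shape 100, scale 6.8
gamma_from_moments <- function(mean, se) {
  if (se == 0) return(list(shape = NA_real_, scale = NA_real_,
                           degenerate = TRUE))
  if (mean <= 0) stop("gamma mean must be > 0", call. = FALSE)
  list(shape = (mean / se)^2, scale = se^2 / mean, degenerate = FALSE)
}

# one random draw for a registry row; truncation by resampling
draw_parameter <- function(meta) {
  m <- meta$mean; se <- meta$se
  if (se == 0) return(m)
  if (meta$family == "beta" && (m <= 0 || m >= 1)) return(m)
  draw <- switch(meta$family,
    normal = function() stats::rnorm(1, m, se),
    beta = {
      sh <- beta_from_moments(m, se)
      function() stats::rbeta(1, sh$alpha, sh$beta)
    },
    gamma = {
      sh <- gamma_from_moments(m, se)
      function() stats::rgamma(1, shape = sh$shape, scale = sh$scale)
    },
    stop("unknown family: ", meta$family, call. = FALSE))
  for (i in 1:1000) {
    v <- draw()
    if (v >= meta$lower && v <= meta$upper) return(v)
  }
  m # pathological truncation; fall back to the mean
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo uncertainty analysis: each replication independently redraws
#' every uncertain parameter from its distribution (beta for probabilities
#' and incidences, gamma for costs and resource use, normal for utilities
#' and efficacy means, truncated to the domain by resampling), rebuilds the
#' transition matrices, runs both strategies, and records the incremental
#' cost and QALYs. A master seed spawns one sub-seed per replication, so
#' results are reproducible and stable under any evaluation order.
#'
#' @param p A `namd_params` object.
#' @param n_reps Number of replications (default 1000).
#' @param seed Master integer seed.
#' @param wtp Willingness-to-pay for the summary (default from settings).
#' @param life_table Life table used for every replication.
#' @param wtp_grid Thresholds for the cost-effectiveness acceptability
#'   curve.
#' @return Object of class `namd_psa`: list with `samples` (one row per
#'   replication: `delta_qaly`, `delta_cost`, `label`, `nmb`), `summary`
#'   (fractions dominant / cost-effective / not cost-effective at `wtp`,
#'   mean increments), and `ceac` (data.frame `wtp`, `prob_cost_effective`).
#' @export
run_psa <- function(p, n_reps = 1000, seed = 1,
                    wtp = p$settings$wtp,
                    life_table = generate_life_table(),
                    wtp_grid = seq(0, 100000, by = 10000)) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  reg <- uncertain_parameters(p)
  paths <- attr(reg, "paths")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  dq <- dc <- numeric(n_reps)
  lab <- character(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    pr <- p
    for (i in seq_len(nrow(reg)))
      pr <- set_param_value(pr, paths[[i]], draw_parameter(reg[i, ]))
    res <- run_comparison(pr, life_table = life_table)
    dq[r] <- res$delta_qaly; dc[r] <- res$delta_cost; lab[r] <- res$label
  }
  nmb <- net_monetary_benefit(dc, dq, wtp)
  samples <- data.frame(rep = seq_len(n_reps), delta_qaly = dq,
                        delta_cost = dc, label = lab, nmb = nmb)
  frac_dom <- mean(lab == "dominant")
  frac_ce <- mean(nmb > 0 & lab != "dominant")
  summary <- list(
    n_reps = n_reps, seed = seed, wtp = wtp,
    fraction_dominant = frac_dom,
    fraction_cost_effective = frac_ce,
    fraction_not_cost_effective = 1 - frac_dom - frac_ce,
    mean_delta_qaly = mean(dq), mean_delta_cost = mean(dc),
    se_delta_qaly = stats::sd(dq) / sqrt(n_reps),
    se_delta_cost = stats::sd(dc) / sqrt(n_reps))
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(w)
      mean(net_monetary_benefit(dc, dq, w) > 0), numeric(1)))
  out <- list(samples = samples, summary = summary, ceac = ceac)
  class(out) <- "namd_psa"
  out
}

#' @export
print.namd_psa <- function(x, ...) {
  s <- x$summary
  cat("<namd_psa>", s$n_reps, "replications (seed", paste0(s$seed, ")\n"))
  cat(sprintf("  dominant            : %.1f%%\n", 100 * s$fraction_dominant))
  cat(sprintf("  cost-effective @WTP : %.1f%% (WTP EUR %s/QALY)\n",
              100 * s$fraction_cost_effective,
              format(s$wtp, big.mark = ",")))
  cat(sprintf("  mean dQALY %+.4f (SE %.4f); mean dcost EUR %+.0f (SE %.0f)\n",
              s$mean_delta_qaly, s$se_delta_qaly,
              s$mean_delta_cost, s$se_delta_cost))
  invisible(x)
}
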