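#' Incremental cost-effectiveness ratio and dominance classification
#'
#' ICER = delta_cost / delta_qaly when delta_qaly != 0. A strategy is
#' "dominant" when it gains QALYs at no extra cost (at least one strict),
#' "dominated" in the mirror case. Trade-off quadrants are labelled
#' "north-east quadrant" (more QALYs, more cost) and "south-west quadrant"
#' (fewer QALYs, lower cost). Equal QALYs yield an undefined ratio labelled
#' by the sign of the cost difference; equal on both axes is "equivalent".
#'
#' @param delta_cost Incremental cost (euros), intervention minus comparator.
#' @param delta_qaly Incremental QALYs.
#' @return List with `icer` (numeric or NA) and `label`.
#' @export
#' @examples
#' compute_icer(-15679, 0.11) # dominant, ratio about -142,536
compute_icer <- function(delta_cost, delta_qaly) {
  if (!is.finite(delta_cost) || !is.finite(delta_qaly))
    stop("increments must be finite", call. = FALSE)
  if (delta_qaly == 0 && delta_cost == 0)
    return(list(icer = NA_real_, label = "equivalent"))
  if (delta_qaly == 0) {
    lab <- if (delta_cost < 0) "equal QALYs, cost-saving"
           else "equal QALYs, costlier"
    return(list(icer = NA_real_, label = lab))
  }
  icer <- delta_cost / delta_qaly
  label <-
    if (delta_qaly >= 0 && delta_cost <= 0) "dominant"
    else if (delta_qaly <= 0 && delta_cost >= 0) "dominated"
    else if (delta_qaly > 0) "north-east quadrant"
    else "south-west quadrant"
  list(icer = icer, label = label)
}

#' Net monetary benefit
#' @param delta_cost,delta_qaly Increments (intervention minus comparator).
#' @param wtp Willingness-to-pay threshold (euros/QALY).
#' @return delta_qaly * wtp - delta_cost.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp = 50000) {
  delta_qaly * wtp - delta_cost
}

#' Run the pairwise cost-utility comparison
#'
#' Builds both strategies' transition matrices, runs both cohorts on the
#' same life table, aggregates discounted outcomes and costs, and computes
#' increments, the ICER/dominance classification and the net monetary
#' benefit at the configured willingness-to-pay.
#'
#' @param p A validated `namd_params` object.
#' @param life_table A `namd_life_table` (default: synthetic
#'   Gompertz-Makeham table).
#' @param intervention,comparator Strategy names (defaults: the first two
#'   strategies, brolucizumab vs aflibercept).
#' @param perspective Overrides `p$settings$perspective` when given.
#' @return Object of class `namd_cea`: per-strategy results plus
#'   `delta_cost`, `delta_qaly`, `icer`, `label`, `nmb`, `perspective`,
#'   `horizon`.
#' @export
run_comparison <- function(p, life_table = generate_life_table(),
                           intervention = strategies(p)[1],
                           comparator = strategies(p)[2],
                           perspective = p$settings$perspective) {
  res <- lapply(c(intervention, comparator), function(st) {
    tr <- run_cohort(st, p, life_table = life_table)
    list(trace = tr,
         agg = aggregate_results(tr, p, st, perspective))
  })
  names(res) <- c(intervention, comparator)
  a <- res[[intervention]]$agg
  b <- res[[comparator]]$agg
  dq <- a$outcomes$qaly - b$outcomes$qaly
  dc <- a$costs$total - b$costs$total
  ic <- compute_icer(dc, dq)
  out <- list(
    intervention = intervention, comparator = comparator,
    results = res,
    delta_qaly = dq, delta_cost = dc,
    delta_ly = a$outcomes$ly - b$outcomes$ly,
    icer = ic$icer, label = ic$label,
    nmb = net_monetary_benefit(dc, dq, p$settings$wtp),
    wtp = p$settings$wtp,
    perspective = perspective, horizon = p$settings$horizon
  )
  class(out) <- "namd_cea"
  out
}

#' Run a named analysis scenario
#'
#' @param p A `namd_params` object (defaults when NULL).
#' @param scenario One of `"base_nhs"` (NHS perspective, 15-year horizon),
#'   `"societal"`, `"horizon40"`, or `"custom"` (settings taken from `p`
#'   plus `overrides`).
#' @param life_table Life table to use for both strategies.
#' @param overrides Named list of configuration overrides applied on top of
#'   `p` (same key tree as [load_parameters()]).
#' @return A `namd_cea` object.
#' @export
run_scenario <- function(p = NULL,
                         scenario = c("base_nhs", "societal", "horizon40",
                                      "custom"),
                         life_table = generate_life_table(),
                         overrides = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(p)) p <- default_parameter_set()
  if (!is.null(overrides)) p <- merge_params(p, overrides)
  p <- switch(scenario,
    base_nhs  = merge_params(p, list(settings = list(perspective = "nhs"))),
    societal  = merge_params(p, list(settings = list(perspective = "societal"))),
    horizon40 = merge_params(p, list(settings = list(horizon = 40))),
    custom    = p)
  viol <- validate_parameters(p)
  if (length(viol))
    stop("invalid parameter set:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  res <- run_comparison(p, life_table = life_table)
  res$scenario <- scenario
  res
}

# apply overrides to an in-memory parameter set (same semantics as config)
merge_params <- function(p, overrides) {
  p2 <- merge_overrides(unclass(p), overrides)
  class(p2) <- "namd_params"
  p2
}

#' @export
print.namd_cea <- function(x, ...) {
  cat("<namd_cea>", x$intervention, "vs", x$comparator,
      sprintf("(%s perspective, %d-year horizon)\n", x$perspective, x$horizon))
  for (st in c(x$intervention, x$comparator)) {
    a <- x$results[[st]]$agg
    cat(sprintf("  %-14s LY %.2f  QALY %.2f  cost EUR %s\n", st,
                a$outcomes$ly, a$outcomes$qaly,
                format(round(a$costs$total), big.mark = ",")))
  }
  cat(sprintf("  increments     dQALY %+.4f  dcost EUR %+.0f\n",
              x$delta_qaly, x$delta_cost))
  cat("  ICER          ",
      if (is.na(x$icer)) x$label else
        sprintf("%s EUR/QALY (%s)", format(round(x$icer), big.mark = ","),
                x$label), "\n")
  invisible(x)
}
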