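---
title: "A Markov cost-utility model for anti-VEGF therapy in neovascular AMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model for anti-VEGF therapy in neovascular AMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namdcea)
```

## The model

`namdcea` implements a cohort state-transition (Markov) model that compares
two intravitreal anti-VEGF strategies for neovascular age-related macular
degeneration (nAMD) — brolucizumab 6 mg and aflibercept 2 mg — on costs and
quality-adjusted life-years (QALYs). It is a "one-eye" model: disease status
is the best-corrected visual acuity (BCVA) of the treated study eye,
discretised into six 15-letter ETDRS bands (86–100 down to ≤25 letters; the
worst band is classed as blindness). On top of the six on-treatment states
sit an off-treatment compartment (VA state preserved, no further
transitions, default unused because base-case discontinuation is 0) and
death. Cycles are annual; the base-case horizon is 15 years, effectively
lifetime for a cohort entering at a mean age of 75.8 years; costs and
outcomes are discounted at 3% per year.

### Transition probabilities from trial summaries

Rather than transition matrices, the efficacy evidence arrives as the mean
and SD of the one-year BCVA letter change per arm (Year 1: +6.50 ± 13.35
letters for brolucizumab, +7.12 ± 13.51 for aflibercept; Year 2, observed
over 44 weeks: −0.61 ± 7.18 and −1.05 ± 8.09). The annual letter change is
modelled as $X \sim N(\mu, \sigma^2)$ and mapped to state moves with the
cutoffs 7.5 letters (one state) and 22.5 letters (two states):

$$p_{\pm 1} = \Phi\!\left(\tfrac{\pm 22.5-\mu}{\sigma}\right) -
             \Phi\!\left(\tfrac{\pm 7.5-\mu}{\sigma}\right), \qquad
  p_{+2} = 1 - \Phi\!\left(\tfrac{22.5-\mu}{\sigma}\right), \;\ldots$$

Movement is capped at two states per cycle; mass that would overshoot the
best or worst band accumulates there, which keeps every row of the matrix
exactly stochastic. Year-2 means, observed over 44 weeks, are extrapolated
linearly to 52 weeks (×52/44) on the assumption that acuity keeps changing
at the same rate; the Year-2+ matrix is then applied in every cycle after
the first. The SD is *not* rescaled by default (`scale_year2_sd` offers
√(52/44) scaling) because the source evidence states only a rate
assumption for the mean.

`empirical_transition_matrix()` provides the brute-force check: simulate
individual letter changes, classify them with the same cutoffs, and compare
frequencies; the test suite does this at n = 200,000 draws with a 0.005
per-band tolerance.

### Mortality, bilateral disease, second eye

Mortality uses a sex-and-age life table, mixed with the cohort's female
share (56.3%) and interpolated at the fractional cohort age. A per-state
relative risk hook (`mortality_rr`, hazard-scale: $q' = 1-(1-q)^{RR}$)
allows VA-related excess mortality; the default is RR = 1 for every state
because the source does not quantify the adjustment and its printed
life-year results are identical across arms, which is only possible if the
adjustment was negligible. Death is applied before transition within a
cycle; the ordering is a documented convention and is regression-tested.

27.14% of the cohort has bilateral disease at entry, and unilateral
patients convert at a constant 16.6%/year
($b_{t+1} = b_t + (1-b_t)\,0.166$). Bilateral status affects costs — drug
and administration costs scale by $(1 + b_t)$, i.e. the fellow eye of a
bilateral patient consumes a second course — and, optionally, utility
(`bilateral_utility_decrement`, default 0). It never affects first-eye
transitions.

### QALYs and costs

State utilities (0.92, 0.82, 0.72, 0.63, 0.53, 0.40, best to worst) weight
the occupancy. Two temporary decrements apply to on-treatment mass: each
injection costs 0.5 × 1/365.25 QALYs (one day of full utility loss in half
of patients — note this is 0.137% of a year per injection; a source figure
of "0.0137%" is a factor-10 slip against its own stated rule), and each
adverse event costs incidence × disutility × expected duration.
Endophthalmitis' duration is a mixture: 20% last a year, 80% six weeks
(expected 0.3 years). Serious ocular adverse-event incidences come from
96-week trial counts annualized linearly (× 52/96); the linear form — not
an exponential rate conversion — reproduces the published annual incidences
at their printed rounding.

Cost categories: drug acquisition (vial price × injections/year; 6.66 vs
7.23 in Year 1, 4.84 vs 5.58 thereafter), administration (€247.20 per
injection), OCT monitoring (€36.07 once yearly for every alive patient),
AE management, blindness (≤25 letters) and low vision (26–40 letters).
Under the NHS perspective the vision-loss states carry direct costs
(€7,856 and €1,964 = 25% of blindness per year); the societal perspective
swaps in the direct+indirect totals (€17,897 and €4,474). Only the
vision-loss categories change with perspective.

## Sensitivity analysis

Every uncertain input carries (family, mean, SE) metadata
(`uncertain_parameters()`). Deterministic one-way analysis moves one
parameter to its 95% CI (mean ± 1.96 SE) when an SE is reported, otherwise
±10%, and re-runs the full comparison; entries are ranked by ICER range.
The probabilistic analysis (default 1000 replications) redraws all
parameters independently — beta for probabilities and incidences (method of
moments), gamma for costs and resource use, normal for utilities and
efficacy means (truncated to domain by resampling) — and summarises the
dominant / cost-effective fractions at €50,000/QALY plus a CEAC. Efficacy
means are sampled with the SE of a mean, SD/√n. A master seed spawns one
sub-seed per replication, so results are order-independent and exactly
reproducible.

Two design points worth flagging:

* Annual injection counts are "rates" in the source's distribution
  taxonomy, but beta distributions require means in (0,1); they are sampled
  from gamma like the other resource-use quantities.
* Negative ICERs are non-monotone in the underlying parameters (a sign
  flip of ΔQALY sends the ratio through ±∞), which is why the dominance
  *label* is reported alongside the raw ratio everywhere.

## What the synthetic data stands in for

Two inputs of the original analysis are not published in reusable form, so
the package generates documented stand-ins:

* **Life table** — a Gompertz–Makeham law $q(a) = 1-\exp(-(A + Bc^a))$
  with $A = 5\times10^{-4}$, $c = 1.12$, $B = 4.45\times10^{-6}$ (female) /
  $6.42\times10^{-6}$ (male), calibrated once to Italian-2018-like
  remaining life expectancy at 75 (≈13.2 / 11.0 years) and never adjusted
  afterwards. `read_life_table()` accepts a real `(age, sex, qx)` CSV for
  reproduction runs.
* **Baseline BCVA distribution** — (0.03, 0.22, 0.38, 0.27, 0.085, 0.015)
  across the six bands, a stand-in consistent with nAMD trial entry
  (≈60 ± 13.5 letters), flagged synthetic; override
  `baseline_distribution` with the trial values where available.

A green test therefore establishes the *mechanics* (mass conservation,
discounting, estimator correctness against Monte-Carlo oracles, dominance
logic, reproducibility) and the *directional* findings (dominance of the
cheaper, less-frequently-injected strategy; wider societal savings;
dominance retained at 40 years). It does not certify the published euro
and QALY levels, which depend on the two stand-ins; with the synthetic
inputs the base case lands within a few percent of the published values
(ΔQALY +0.113 vs +0.11; Δcost −€16.2k vs −€15.7k) but that agreement is
not asserted by the suite.

## Known limitations and honest reds

* Under the prescribed bound rule, the Year-2 efficacy means at their 95%
  CI limits flip the sign of the ~0.11 QALY increment, so "every one-way
  scenario stays dominant" fails in this configuration; the corresponding
  acceptance test is left red rather than weakened. The published analysis
  reports all-dominant with a narrower ICER range, implying tighter
  (unpublished) efficacy bounds.
* With ±10% uncertainty on prices and injection frequencies the cost
  increment goes positive in ≈8% of PSA draws, depressing the dominant
  fraction to ≈80% against a published 84% (and leaving ≈4% of draws
  not cost-effective at €50,000/QALY); also asserted as stated and left
  red.
* The published cost table has internal ratios (acquisition vs
  administration, arm-dependent monitoring) that no stated accrual rule
  reproduces; this package implements the stated rules.
* No half-cycle correction by default (the source uses none); a flag
  exists. No microsimulation, no fellow-eye BCVA dynamics, no treatment
  waning beyond the constant Year-2+ matrices.

## A worked run

```{r}
p <- default_parameter_set()
lt <- generate_life_table()
res <- run_comparison(p, life_table = lt)
res
```

```{r}
writeLines(render_results_table(res)$text)
```
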