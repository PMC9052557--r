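test_that("discount factors", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03) # 0.970874
  expect_equal(discount_factor(1, 0.03), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(1, -0.1), "rate")
})

test_that("injection disutility follows the 50% x 1 day rule", {
  expect_equal(annual_injection_disutility(6.66), 6.66 * 0.5 / 365.25)
  expect_equal(annual_injection_disutility(6.66), 0.009117, tolerance = 1e-4)
  expect_equal(annual_injection_disutility(7.23), 0.009897, tolerance = 1e-4)
  expect_equal(annual_injection_disutility(0), 0)
  # per-injection loss is 0.137% of a full-utility year at the defaults
  expect_equal(annual_injection_disutility(1), 0.00137, tolerance = 1e-3)
  expect_error(annual_injection_disutility(-1), ">= 0")
})

test_that("AE disutility sums incidence x disutility x expected duration", {
  dur <- list(endophthalmitis = list(years = c(1, 1.5 / 12),
                                     weights = c(0.2, 0.8)))
  expect_equal(ae_expected_duration(dur$endophthalmitis), 0.3)
  expect_equal(
    annual_ae_disutility(c(endophthalmitis = 0.0030),
                         c(endophthalmitis = 0.3), dur),
    0.0030 * 0.3 * 0.3) # 0.00027
  # zero-disutility events contribute nothing
  expect_equal(
    annual_ae_disutility(c(retinal_tear = 0.5), c(retinal_tear = 0),
                         list(retinal_tear = list(years = 0, weights = 1))),
    0)
  expect_equal(annual_ae_disutility(numeric(0), numeric(0), list()), 0)
})

make_row <- function(on = rep(0, 6), off = rep(0, 6), bilateral = 0) {
  alive <- sum(on) + sum(off)
  data.frame(cycle = 1, age = 76.8,
             t(stats::setNames(on, paste0("on_", va_states))),
             t(stats::setNames(off, paste0("off_", va_states))),
             on = sum(on), off = sum(off), alive = alive,
             dead = 1 - alive, bilateral = bilateral, check.names = FALSE)
}

test_that("cycle QALYs weigh occupancy by state utility minus decrements", {
  p <- p_default
  # whole cohort in the best state, no treatment (off), no decrements
  row <- make_row(off = c(1, 0, 0, 0, 0, 0))
  expect_equal(cycle_qalys(row, p, "brolucizumab", "year1")$total, 0.92)
  # whole cohort dead
  expect_equal(cycle_qalys(make_row(), p, "brolucizumab", "year1")$total, 0)
  # 50/50 split best/worst, no decrements
  row <- make_row(off = c(0.5, 0, 0, 0, 0, 0.5))
  expect_equal(cycle_qalys(row, p, "brolucizumab", "year1")$total, 0.66)
  # on-treatment mass also accrues injection and AE disutilities
  row_on <- make_row(on = c(1, 0, 0, 0, 0, 0))
  q <- cycle_qalys(row_on, p, "brolucizumab", "year1")
  expect_equal(q$injection_disutility, annual_injection_disutility(6.66))
  expect_lt(q$total, 0.92)
  expect_equal(q$total,
               0.92 - q$injection_disutility - q$ae_disutility)
})

test_that("cycle costs follow the per-category accrual rules", {
  p <- p_default
  row <- make_row(on = c(0, 0, 1, 0, 0, 0)) # unilateral, on treatment
  cc <- cycle_costs(row, p, "brolucizumab", "year1", "nhs")
  expect_equal(cc[["acquisition"]], 680 * 6.66) # 4528.80
  expect_equal(cc[["administration"]], 247.20 * 6.66) # 1646.352
  expect_equal(cc[["monitoring"]], 36.07)
  inc <- p$adverse_events$incidence$brolucizumab
  expect_equal(cc[["ae_management"]], sum(inc * p$costs$ae_unit))
  expect_equal(cc[["blindness"]], 0)
  expect_equal(cc[["total"]], sum(cc[names(cc) != "total"]))

  # all alive but off treatment in 71-85: only monitoring accrues
  row <- make_row(off = c(0, 1, 0, 0, 0, 0))
  cc <- cycle_costs(row, p, "brolucizumab", "year1", "nhs")
  expect_equal(unname(cc[c("acquisition", "administration", "ae_management",
                           "blindness", "low_vision")]), rep(0, 5))
  expect_equal(cc[["monitoring"]], 36.07)

  # bilateral patients double drug and administration use
  row_uni <- make_row(on = c(0, 0, 1, 0, 0, 0), bilateral = 0)
  row_bil <- make_row(on = c(0, 0, 1, 0, 0, 0), bilateral = 1)
  cc_u <- cycle_costs(row_uni, p, "aflibercept", "year2", "nhs")
  cc_b <- cycle_costs(row_bil, p, "aflibercept", "year2", "nhs")
  expect_equal(cc_b[["acquisition"]], 2 * cc_u[["acquisition"]])
  expect_equal(cc_b[["administration"]], 2 * cc_u[["administration"]])
  expect_equal(cc_b[["monitoring"]], cc_u[["monitoring"]])
  expect_equal(cc_u[["acquisition"]], 740 * 5.58)

  # blindness / low-vision mapping and perspective switch
  row <- make_row(off = c(0, 0, 0, 0, 0.3, 0.7))
  nhs <- cycle_costs(row, p, "brolucizumab", "subsequent", "nhs")
  soc <- cycle_costs(row, p, "brolucizumab", "subsequent", "societal")
  expect_equal(nhs[["blindness"]], 7856 * 0.7)
  expect_equal(nhs[["low_vision"]], 1964 * 0.3)
  expect_equal(soc[["blindness"]], 17897 * 0.7)
  expect_equal(soc[["low_vision"]], 4474 * 0.3)
  same <- c("acquisition", "administration", "monitoring", "ae_management")
  expect_equal(nhs[same], soc[same])
  expect_error(cycle_costs(row, p, "brolucizumab", "year1", "martian"),
               "perspective")
})

test_that("aggregate matches an independent 3-cycle spreadsheet oracle", {
  # frozen values: independent recomputation (numpy/scipy) of a 3-cycle
  # brolucizumab run with flat 10% annual mortality, NHS perspective
  p <- with_settings(p_default, horizon = 3)
  tr <- run_cohort("brolucizumab", p, life_table = flat_life_table(0.1))
  agg <- aggregate_results(tr, p, "brolucizumab", "nhs")
  expect_equal(agg$outcomes$ly, 2.3044273638, tolerance = 1e-9)
  expect_equal(agg$outcomes$qaly, 1.6734880163, tolerance = 1e-9)
  expect_equal(agg$costs$acquisition, 12725.37176373, tolerance = 1e-9)
  expect_equal(agg$costs$administration, 4626.04691176, tolerance = 1e-9)
  expect_equal(agg$costs$monitoring, 83.12069501, tolerance = 1e-9)
  expect_equal(agg$costs$ae_management, 29.31798243, tolerance = 1e-9)
  expect_equal(agg$costs$blindness, 625.20662660, tolerance = 1e-9)
  expect_equal(agg$costs$low_vision, 405.83854671, tolerance = 1e-9)
  expect_equal(agg$costs$total, 18494.90252625, tolerance = 1e-9)
})

test_that("aggregate properties: discounting, trivial traces, components", {
  p <- p_default
  tr <- run_cohort("brolucizumab", p, life_table = lt_synth)
  agg <- aggregate_results(tr, p)
  # QALYs bounded by LYs times the best utility
  expect_lte(agg$outcomes$qaly, agg$outcomes$ly * max(p$utilities))
  # discounted strictly below undiscounted at a positive rate
  expect_lt(agg$outcomes$qaly, agg$undiscounted$outcomes$qaly)
  expect_lt(agg$costs$total, agg$undiscounted$costs$total)
  # zero rate: equal
  p0 <- with_settings(p, discount_rate = 0)
  agg0 <- aggregate_results(run_cohort("brolucizumab", p0,
                                       life_table = lt_synth), p0)
  expect_equal(agg0$outcomes$qaly, agg0$undiscounted$outcomes$qaly)
  # single cycle, no discounting: aggregate equals the cycle values
  p1 <- with_settings(p, horizon = 1, discount_rate = 0)
  tr1 <- run_cohort("brolucizumab", p1, life_table = lt_synth)
  agg1 <- aggregate_results(tr1, p1)
  cc1 <- cycle_costs(tr1[2, ], p1, "brolucizumab", "year1", "nhs")
  expect_equal(agg1$costs$total, cc1[["total"]])
  expect_equal(agg1$outcomes$qaly,
               cycle_qalys(tr1[2, ], p1, "brolucizumab", "year1")$total)
  # perspective switch changes only the vision-loss categories
  soc <- aggregate_results(tr, p, perspective = "societal")
  expect_equal(soc$costs$acquisition, agg$costs$acquisition)
  expect_equal(soc$costs$monitoring, agg$costs$monitoring)
  expect_gt(soc$costs$blindness, agg$costs$blindness)
  expect_gt(soc$costs$low_vision, agg$costs$low_vision)
})

test_that("removing all AEs raises QALYs and lowers costs", {
  p <- p_default
  pz <- p
  for (st in strategies(p))
    pz$adverse_events$incidence[[st]][] <- 0
  tr <- run_cohort("brolucizumab", p, life_table = lt_synth)
  a1 <- aggregate_results(tr, p)
  a2 <- aggregate_results(run_cohort("brolucizumab", pz,
                                     life_table = lt_synth), pz)
  expect_gt(a2$outcomes$qaly, a1$outcomes$qaly)
  expect_lt(a2$costs$total, a1$costs$total)
})

test_that("half-cycle correction averages adjacent cycles", {
  p <- with_settings(p_default, half_cycle_correction = TRUE)
  tr <- run_cohort("brolucizumab", p, life_table = lt_synth)
  hcc <- aggregate_results(tr, p)
  std <- aggregate_results(tr, with_settings(p_default))
  # survival declines, so averaging with the cycle start adds life-years
  expect_gt(hcc$outcomes$ly, std$outcomes$ly)
})
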