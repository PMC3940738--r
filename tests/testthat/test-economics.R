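test_that("present values reduce to simple sums and match closed forms", {
  expect_equal(present_value_annuity(100, 7, rate = 0), 700)
  expect_equal(present_value_annuity(1925, 4, 0.03, "cycle_end"),
               1925 * sum(1.03^-(1:4)), tolerance = 1e-12)
  expect_equal(present_value_annuity(1925, 8, 0.03, "cycle_end"),
               1925 * sum(1.03^-(1:8)), tolerance = 1e-12)
  expect_equal(present_value_annuity(10, 3, 0.03, "cycle_start"),
               10 * sum(1.03^-(0:2)), tolerance = 1e-12)
  expect_error(present_value_annuity(1, 4, rate = -1.5), "rate")
  expect_error(present_value_annuity(1, 0), "horizon")
})

test_that("offsets vanish when their drivers are zero", {
  pp0 <- productivity_params(annual_earnings_premium = 0,
                             annual_missed_day_reduction = 0,
                             recovery_days = 0)
  expect_equal(earnings_offset(pp0, 4), 0)
  expect_equal(missed_workday_offset(pp0, 4), 0)
})

test_that("the recovery absenteeism dominates the 4-year missed-day benefit", {
  pp <- productivity_params()
  off <- missed_workday_offset(pp, 4)
  expect_lt(off, 0)
  expect_gt(off, -2500)
  # and the survival-weighted variant stays negative of similar size
  surv <- rep(0.99, 4)
  off2 <- missed_workday_offset(pp, 4, survival = surv)
  expect_lt(off2, 0)
})

test_that("four-year present value of the missed-day reduction is about 11 days", {
  days_pv <- 3 * sum(1.03^-(1:4))
  expect_equal(days_pv, 11.15, tolerance = 0.01)
})

test_that("the net-cost identity and ICER arithmetic hold on the published overall row", {
  surg <- list(total_cost = 30900, total_qaly = 3.04, horizon = 4L)
  nons <- list(total_cost = 14402, total_qaly = 2.73, horizon = 4L)
  r <- compute_icer(surg, nons, offsets = list(earnings = 7251, missed_workdays = -1648))
  expect_identical(r$net_cost_surgical, 30900 - 7251 + 1648)
  expect_equal(r$net_cost_surgical, 25297)
  expect_equal(r$icer, (25297 - 14402) / (3.04 - 2.73), tolerance = 1e-12)
})

test_that("identical arms raise the undefined-dominance flag", {
  arm <- list(total_cost = 1000, total_qaly = 2, horizon = 4L)
  r <- compute_icer(arm, arm)
  expect_true(r$undefined)
  expect_true(is.na(r$icer))
})

test_that("negative net incremental cost is reported as cost-saving, never a negative ratio", {
  surg <- list(total_cost = 10000, total_qaly = 3, horizon = 8L)
  nons <- list(total_cost = 14000, total_qaly = 2.7, horizon = 8L)
  r <- compute_icer(surg, nons)
  expect_true(r$cost_saving)
  expect_true(is.na(r$icer))
  expect_equal(r$net_savings, 4000)
})

test_that("mismatched horizons are rejected", {
  surg <- list(total_cost = 1, total_qaly = 1, horizon = 4L)
  nons <- list(total_cost = 1, total_qaly = 0.5, horizon = 8L)
  expect_error(compute_icer(surg, nons), "horizon")
})

test_that("including positive offsets can only lower the ICER", {
  cfg <- default_config()
  with_p <- run_cea(cfg, 4, "overall", TRUE)
  without_p <- run_cea(cfg, 4, "overall", FALSE)
  expect_gt(with_p$earnings_offset + with_p$missed_workday_offset, 0)
  expect_lt(with_p$icer, without_p$icer)
})

test_that("the ICER rises with surgery cost and falls with surgical success", {
  cfg <- validate_config(config_forty())
  base <- run_cea(cfg, 4)$icer
  set <- discectomyCEA:::sens_setters()
  expect_gt(run_cea(set$surgery_cost(cfg, 18065), 4)$icer, base)
  expect_lt(run_cea(set$p_satisfactory_surgical(cfg, 0.803), 4)$icer, base)
})

test_that("the horizon sweep ICER never increases and flags cost savings", {
  cfg <- default_config()
  sw <- horizon_sweep(cfg, 1:12, "outpatient")
  vals <- ifelse(sw$cost_saving, -Inf, sw$icer)
  defined <- vals[is.finite(vals)]
  expect_true(all(diff(defined) <= 1e-6))
  # once cost-saving, always cost-saving
  cs <- which(sw$cost_saving)
  if (length(cs)) expect_identical(cs, seq(min(cs), nrow(sw)))
  expect_false(is.na(attr(sw, "cost_saving_threshold")))
})
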