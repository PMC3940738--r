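base_params <- clinical_params()
base_util <- utility_set()
base_costs <- cost_params()
base_timing <- timing_convention()

test_that("nonsurgical transitions are stay-or-die and rows sum to one", {
  lt <- default_life_table()
  for (cyc in c(1, 2, 5)) {
    P <- build_transitions(base_params, lt, 45, cyc, "nonsurgical")
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
    # from outcome states, only staying put or dying is possible
    for (s in c("Sat0", "Unsat0")) {
      nz <- colnames(P)[P[s, ] > 0]
      expect_true(all(nz %in% c(s, "Dead")))
    }
  }
})

test_that("zero mortality and zero revision rates give an identity map on alive states", {
  p <- clinical_params(revision_rate_year1 = 0, revision_rate_subsequent = 0,
                       surgical_mortality = 0)
  P <- build_transitions(p, zero_life_table(), 45, 2, "surgical")
  outcome <- grep("^(Sat|Unsat)", rownames(P), value = TRUE)
  expect_equal(P[outcome, outcome], diag(length(outcome)),
               ignore_attr = TRUE, tolerance = 1e-15)
  # revision states are unreachable from any occupied state
  expect_true(all(P[outcome, grep("^Rev", colnames(P))] == 0))
})

test_that("the first cycle uses the first-year revision rate, later cycles the subsequent rate", {
  lt <- zero_life_table()
  P1 <- build_transitions(base_params, lt, 45, 1, "surgical")
  P3 <- build_transitions(base_params, lt, 45, 3, "surgical")
  mu <- base_params$surgical_mortality
  expect_equal(P1["Sat0", "Rev1"], 0.06 * (1 - mu), tolerance = 1e-12)
  expect_equal(P3["Sat0", "Rev1"], 0.03 * (1 - mu), tolerance = 1e-12)
})

test_that("ages outside the life table are rejected", {
  expect_error(build_transitions(base_params, default_life_table(), 110, 1, "surgical"),
               "life-table")
})

test_that("conservation: occupancy sums to one every cycle with all utilities one", {
  u1 <- utility_set(1, 1, 1, 0)
  p <- clinical_params(surgical_mortality = 0)
  t0 <- timing_convention(discount_rate = 0)
  tr <- run_cohort("surgical", p, u1, base_costs, zero_life_table(), t0, 45, 4)
  expect_equal(tr$total_qaly, 4, tolerance = 1e-12)
})

test_that("nonsurgical QALYs match the closed-form annuity oracle", {
  # hand oracle: (p*u_sat + (1-p)*u_unsat) * sum_{t=0..3} 1.03^-t
  tr <- run_cohort("nonsurgical", base_params, base_util, base_costs,
                   zero_life_table(), base_timing, 45, 4)
  expected <- (0.485 * 0.89 + 0.515 * 0.56) * sum(1.03^-(0:3))
  expect_equal(tr$total_qaly, expected, tolerance = 1e-9)
})

test_that("with no revisions the surgical arm matches its closed form", {
  p <- clinical_params(revision_rate_year1 = 0, revision_rate_subsequent = 0)
  tr <- run_cohort("surgical", p, base_util, base_costs, zero_life_table(),
                   base_timing, 45, 6)
  mu <- p$surgical_mortality
  per_cycle <- (1 - mu) * (0.753 * 0.89 + 0.247 * 0.56)
  expect_equal(tr$total_qaly, per_cycle * sum(1.03^-(0:5)), tolerance = 1e-10)
})

test_that("engine equals exhaustive path enumeration for small models", {
  qx_vals <- c(0, 0.004, 0.02)
  for (q in qx_vals) {
    for (arm in c("surgical", "nonsurgical")) {
      p <- clinical_params(max_revisions = 1)
      tr <- run_cohort(arm, p, base_util, base_costs, flat_life_table(q),
                       base_timing, 45, 3)
      or <- oracle_cohort(arm, p, base_util, base_costs, function(a) q, 45, 3)
      expect_equal(tr$total_qaly, or$qaly, tolerance = 1e-10)
      expect_equal(tr$total_cost, or$cost, tolerance = 1e-10)
    }
  }
})

test_that("occupancy is conserved for random valid parameter draws", {
  set.seed(2024)
  lt <- default_life_table()
  for (i in 1:200) {
    p <- random_clinical_params()
    tr <- run_cohort(sample(c("surgical", "nonsurgical"), 1), p, base_util,
                     base_costs, lt, base_timing, sample(25:70, 1),
                     sample(1:10, 1))
    st <- markov_states(p$max_revisions)
    sums <- rowSums(tr$trace[, st, drop = FALSE])
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(diff(tr$trace$Dead) >= -1e-15))
    expect_true(all(tr$trace$cum_qaly >= -1e-15) && all(diff(tr$trace$cum_qaly) >= -1e-15))
  }
})

test_that("raising a utility raises QALYs; raising mortality lowers them", {
  lt <- default_life_table()
  base <- run_cohort("surgical", base_params, base_util, base_costs, lt,
                     base_timing, 45, 8)$total_qaly
  up <- run_cohort("surgical", base_params, utility_set(u_satisfactory = 0.95),
                   base_costs, lt, base_timing, 45, 8)$total_qaly
  expect_gte(up, base)
  heavier <- flat_life_table(0.05)
  down <- run_cohort("surgical", base_params, base_util, base_costs, heavier,
                     base_timing, 45, 8)$total_qaly
  expect_lte(down, base)
})

test_that("invalid horizons are rejected", {
  expect_error(run_cohort("surgical", base_params, base_util, base_costs,
                          default_life_table(), base_timing, 45, 0), "horizon")
})

test_that("age weighting is an exact convex combination", {
  lt <- default_life_table()
  runs <- lapply(c(a = 40, b = 60), function(a)
    run_cohort("nonsurgical", base_params, base_util, base_costs, lt,
               base_timing, a, 4))
  # identical inputs -> identical output
  same <- age_weighted_traces(list(a = runs$a, b = runs$a),
                              data.frame(age_group = c("a", "b"), weight = c(0.5, 0.5)))
  expect_equal(same$total_qaly, runs$a$total_qaly, tolerance = 1e-12)
  # degenerate weights pick out one cohort
  one <- age_weighted_traces(runs, data.frame(age_group = c("a", "b"), weight = c(1, 0)))
  expect_equal(one$total_cost, runs$a$total_cost, tolerance = 1e-12)
  expect_error(age_weighted_traces(runs["a"],
               data.frame(age_group = c("a", "b"), weight = c(0.5, 0.5))), "missing")
})

test_that("applying the published age weights to the per-age premiums gives the weighted premium", {
  tab <- productivity_table()
  expect_equal(sum(tab$weight * tab$earnings_change), 1925, tolerance = 2)
})
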