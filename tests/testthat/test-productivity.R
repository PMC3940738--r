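test_that("noiseless data recovers the earnings model exactly", {
  spec <- tiny_spec(n = 400, noise_sd = 0, score_sd = 0.3)
  rec <- generate_population(spec)
  m <- fit_earnings_model(rec)
  expect_equal(m$score_coefficient, spec$earnings_coeffs$score, tolerance = 1e-8)
  expect_equal(m$intercept, spec$earnings_coeffs$intercept, tolerance = 1e-8)
  expect_equal(m$residual_sd, 0, tolerance = 1e-6)
})

test_that("a two-point dataset yields the interpolating line", {
  rec <- data.frame(
    age_group = factor(c("<40", "<40", "<40"), levels = levels(generate_population(tiny_spec(n = 1))$age_group)),
    functional_score = c(0.2, 0.8, 0.2),
    household_earnings = c(30000, 60000, 30000),
    missed_workdays = c(10L, 2L, 10L))
  m <- fit_earnings_model(rec)
  expect_equal(m$score_coefficient, (60000 - 30000) / 0.6, tolerance = 1e-10)
  expect_equal(m$intercept + 0.2 * m$score_coefficient, 30000, tolerance = 1e-8)
})

test_that("degenerate earnings designs raise informative errors", {
  rec <- generate_population(tiny_spec(n = 100, score_sd = 0))
  expect_error(fit_earnings_model(rec), "distinct")
})

test_that("NB2 maximum likelihood recovers simulated coefficients", {
  # strongly negative score effect, moderate dispersion
  cal <- calibrated_coefficients()
  coefs <- list(intercept = 2.5, score = -2, age_offsets = cal$missed_days$age_offsets * 0)
  for (seed in 1:3) {
    spec <- population_spec(n = 1e4, seed = seed, missed_days_coeffs = coefs,
                            nb_dispersion = 5, score_sd = 0.3)
    m <- fit_missed_days_model(generate_population(spec))
    expect_true(m$converged)
    expect_lt(abs(m$score_coefficient - (-2)), 0.2)
    expect_lt(abs(m$dispersion - 5) / 5, 0.25)
  }
})

test_that("NB2 fit agrees with an independent glm.nb fit", {
  skip_if_not_installed("MASS")
  rec <- generate_population(tiny_spec(n = 5000, seed = 9))
  m <- fit_missed_days_model(rec)
  ref <- MASS::glm.nb(missed_workdays ~ functional_score + age_group, data = rec)
  expect_equal(m$score_coefficient, unname(coef(ref)["functional_score"]),
               tolerance = 1e-4)
  expect_equal(m$dispersion, ref$theta, tolerance = 1e-3)
  expect_equal(m$log_lik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("the NB2 likelihood attains at least the Poisson likelihood", {
  # Poisson-like data: enormous dispersion parameter
  spec <- tiny_spec(n = 3000, seed = 21, nb_dispersion = 1e6, score_sd = 0.3)
  rec <- generate_population(spec)
  m <- fit_missed_days_model(rec)
  pois <- glm(missed_workdays ~ functional_score + age_group,
              family = poisson(), data = rec)
  expect_gte(m$log_lik, as.numeric(logLik(pois)) - 1e-6)
})

test_that("all-zero counts are rejected under the log link", {
  rec <- generate_population(tiny_spec(n = 100, score_sd = 0.3))
  rec$missed_workdays <- 0L
  expect_error(fit_missed_days_model(rec), "zero")
})

test_that("identical scores in both arms imply zero change columns", {
  rec <- generate_population(tiny_spec(n = 2000, seed = 2, score_sd = 0.3))
  em <- fit_earnings_model(rec)
  dm <- fit_missed_days_model(rec)
  scores <- productivity_table()[c("age_group", "weight")]
  scores$score_surgical <- 0.8
  scores$score_nonsurgical <- 0.8
  pred <- predict_productivity(em, dm, scores)
  expect_equal(pred$earnings_change, rep(0, nrow(pred)))
  expect_equal(pred$missed_value_change, rep(0, nrow(pred)))
  expect_equal(pred$missed_day_reduction, rep(0, nrow(pred)))
})

test_that("change columns satisfy their defining identities for any fit", {
  rec <- generate_population(tiny_spec(n = 2000, seed = 4, score_sd = 0.3))
  pred <- predict_productivity(fit_earnings_model(rec), fit_missed_days_model(rec))
  expect_equal(pred$earnings_change,
               pred$earnings_surgical - pred$earnings_nonsurgical)
  expect_equal(pred$missed_value_change,
               pred$missed_value_nonsurgical - pred$missed_value_surgical)
  # earnings prediction affine in score; missed days monotone in score
  em <- fit_earnings_model(rec)
  dm <- fit_missed_days_model(rec)
  s <- seq(0, 1, by = 0.25)
  e <- discectomyCEA:::predict_linear(em, s, rep("<40", length(s)))
  expect_equal(diff(e), rep(em$score_coefficient * 0.25, 4), tolerance = 1e-9)
  d <- discectomyCEA:::predict_linear(dm, s, rep("<40", length(s)), exp)
  expect_true(all(diff(d) * sign(dm$score_coefficient) >= 0))
})

test_that("unknown age groups and out-of-range scores are rejected", {
  rec <- generate_population(tiny_spec(n = 2000, seed = 4, score_sd = 0.3))
  em <- fit_earnings_model(rec)
  dm <- fit_missed_days_model(rec)
  scores <- data.frame(age_group = "65+", weight = 1,
                       score_surgical = 0.8, score_nonsurgical = 0.7)
  expect_error(predict_productivity(em, dm, scores), "unknown age group")
  scores2 <- data.frame(age_group = "<40", weight = 1,
                        score_surgical = 1.2, score_nonsurgical = 0.7)
  expect_error(predict_productivity(em, dm, scores2), "\\[0, 1\\]")
})
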