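# Typed parameter bundles for the decision model. Defaults encode the
# published base-case inputs: clinical probabilities and utilities, direct
# medical costs (2009 USD, private-payer level), and the productivity table
# used for the human-capital offsets.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(field, "must be a single probability in [0, 1]")
  x
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_invalid(field, "must be a single non-negative number")
  x
}

#' Clinical transition parameters
#'
#' Base-case clinical inputs of the Markov model: treatment success
#' fractions, revision-surgery rates, perioperative mortality and the cap on
#' the number of revisions a patient may undergo.
#'
#' @param p_satisfactory_surgical Fraction of surgical patients whose first
#'   (non-revision) outcome is satisfactory.
#' @param p_satisfactory_nonsurgical Same fraction for nonsurgical patients.
#' @param p_satisfactory_after_revision Fraction of revision surgeries with a
#'   satisfactory outcome; the base case assumes revision outcomes match
#'   primary surgery.
#' @param revision_rate_year1 Probability of revision surgery during the
#'   first year after the primary operation.
#' @param revision_rate_subsequent Annual revision probability in later
#'   years, applied to alive patients in an outcome state who have not yet
#'   exhausted `max_revisions`.
#' @param surgical_mortality Per-operation mortality, applied at the primary
#'   surgery and again on entry to each revision.
#' @param max_revisions Maximum number of revision surgeries per patient.
#' @return An object of class `clinical_params`.
#' @export
clinical_params <- function(p_satisfactory_surgical = 0.753,
                            p_satisfactory_nonsurgical = 0.485,
                            p_satisfactory_after_revision = 0.753,
                            revision_rate_year1 = 0.06,
                            revision_rate_subsequent = 0.03,
                            surgical_mortality = 0.0013,
                            max_revisions = 2L) {
  out <- list(
    p_satisfactory_surgical = check_prob(p_satisfactory_surgical, "p_satisfactory_surgical"),
    p_satisfactory_nonsurgical = check_prob(p_satisfactory_nonsurgical, "p_satisfactory_nonsurgical"),
    p_satisfactory_after_revision = check_prob(p_satisfactory_after_revision, "p_satisfactory_after_revision"),
    revision_rate_year1 = check_prob(revision_rate_year1, "revision_rate_year1"),
    revision_rate_subsequent = check_prob(revision_rate_subsequent, "revision_rate_subsequent"),
    surgical_mortality = check_prob(surgical_mortality, "surgical_mortality"),
    max_revisions = as.integer(max_revisions))
  if (out$max_revisions < 0L) stop_invalid("max_revisions", "must be >= 0")
  structure(out, class = "clinical_params")
}

#' Health-state utilities
#'
#' Preference weights for the model's health states. The revision state is a
#' temporary state whose utility lies between the satisfactory and
#' unsatisfactory weights; death has utility zero.
#'
#' @param u_satisfactory,u_unsatisfactory,u_revision,u_dead Utility weights
#'   in `[0, 1]`.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_satisfactory = 0.89, u_unsatisfactory = 0.56,
                        u_revision = 0.69, u_dead = 0) {
  out <- list(
    u_satisfactory = check_prob(u_satisfactory, "u_satisfactory"),
    u_unsatisfactory = check_prob(u_unsatisfactory, "u_unsatisfactory"),
    u_revision = check_prob(u_revision, "u_revision"),
    u_dead = check_prob(u_dead, "u_dead"))
  if (out$u_dead != 0) stop_invalid("u_dead", "must be 0")
  if (out$u_revision < min(out$u_satisfactory, out$u_unsatisfactory) ||
      out$u_revision > max(out$u_satisfactory, out$u_unsatisfactory))
    stop_invalid("u_revision", "must lie between the satisfactory and unsatisfactory utilities")
  structure(out, class = "utility_set")
}

#' Direct medical cost parameters
#'
#' Direct medical costs in 2009 USD at private-payer payment levels: the
#' blended surgery payment with its inpatient-only and outpatient-only
#' variants, and the annual non-surgery medical costs of each arm.
#'
#' @param surgery_cost Blended (setting-weighted) payment for the index
#'   discectomy; also used for each revision operation.
#' @param surgery_cost_inpatient,surgery_cost_outpatient Setting-specific
#'   surgery payments.
#' @param annual_medical_surgical,annual_medical_nonsurgical Annual medical
#'   cost per alive patient, excluding surgery, by arm.
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(surgery_cost = 16423,
                        surgery_cost_inpatient = 20585,
                        surgery_cost_outpatient = 11616,
                        annual_medical_surgical = 3208,
                        annual_medical_nonsurgical = 3794) {
  out <- list(
    surgery_cost = check_nonneg(surgery_cost, "surgery_cost"),
    surgery_cost_inpatient = check_nonneg(surgery_cost_inpatient, "surgery_cost_inpatient"),
    surgery_cost_outpatient = check_nonneg(surgery_cost_outpatient, "surgery_cost_outpatient"),
    annual_medical_surgical = check_nonneg(annual_medical_surgical, "annual_medical_surgical"),
    annual_medical_nonsurgical = check_nonneg(annual_medical_nonsurgical, "annual_medical_nonsurgical"))
  if (out$surgery_cost_outpatient > out$surgery_cost ||
      out$surgery_cost > out$surgery_cost_inpatient)
    stop_invalid("surgery_cost", "must satisfy outpatient <= blended <= inpatient")
  structure(out, class = "cost_params")
}

#' Productivity (indirect-cost) parameters
#'
#' Inputs of the human-capital productivity offsets: the annual earnings
#' premium of the surgical arm, the annual reduction in missed workdays and
#' its dollar value, the recovery absenteeism after the index operation, and
#' the daily wage used to value a missed day (1/`workdays_per_year` of the
#' baseline, nonsurgical-arm, annual salary).
#'
#' `annual_missed_value_change` is the dollar value of the annual
#' missed-workday reduction. When the per-arm valuations are known (as in
#' the packaged productivity table, where each arm's days are valued at its
#' own daily wage) it should be supplied directly; otherwise it defaults to
#' `annual_missed_day_reduction * baseline_daily_wage`.
#'
#' @param annual_earnings_premium Surgical minus nonsurgical predicted annual
#'   household earnings, USD/year.
#' @param annual_missed_day_reduction Days/year by which surgery reduces
#'   missed workdays (recovery excluded).
#' @param recovery_days Workdays lost recovering from the index operation.
#' @param workdays_per_year Workdays in a full working year.
#' @param baseline_daily_wage Daily wage used to value missed days, USD.
#' @param annual_missed_value_change USD/year value of the missed-day
#'   reduction; see Details.
#' @return An object of class `productivity_params`.
#' @export
productivity_params <- function(annual_earnings_premium = 1925,
                                annual_missed_day_reduction = 3,
                                recovery_days = 20,
                                workdays_per_year = 240,
                                baseline_daily_wage = 45694 / 240,
                                annual_missed_value_change = NULL) {
  if (is.null(annual_missed_value_change))
    annual_missed_value_change <- annual_missed_day_reduction * baseline_daily_wage
  out <- list(
    annual_earnings_premium = check_nonneg(annual_earnings_premium, "annual_earnings_premium"),
    annual_missed_day_reduction = check_nonneg(annual_missed_day_reduction, "annual_missed_day_reduction"),
    recovery_days = check_nonneg(recovery_days, "recovery_days"),
    workdays_per_year = check_nonneg(workdays_per_year, "workdays_per_year"),
    baseline_daily_wage = check_nonneg(baseline_daily_wage, "baseline_daily_wage"),
    annual_missed_value_change = check_nonneg(annual_missed_value_change, "annual_missed_value_change"))
  if (out$workdays_per_year <= 0) stop_invalid("workdays_per_year", "must be > 0")
  structure(out, class = "productivity_params")
}

#' Discounting and accrual convention
#'
#' Cycle length is one year. Streams may accrue at the start of each cycle
#' (`"cycle_start"`, annuity-due), mid-cycle (`"half_cycle"`) or at the end
#' (`"cycle_end"`, ordinary annuity). The calibrated default accrues
#' utilities, annual medical costs and the productivity offsets at cycle
#' start, weighted by state occupancy (offsets by the surgical arm's
#' survival); recovery absenteeism is valued at the time of surgery,
#' undiscounted, like the index surgery payment itself.
#'
#' @param discount_rate Annual discount rate (default 3%).
#' @param utilities,annual_costs,offsets Accrual timing per stream, one of
#'   `"cycle_start"`, `"half_cycle"`, `"cycle_end"`.
#' @param survival_weight_offsets Should the offset streams be weighted by
#'   the surgical arm's survival curve?
#' @param recovery_timing When the recovery-absenteeism cost accrues:
#'   `"immediate"` (at surgery, undiscounted) or `"first_cycle_end"`.
#' @return An object of class `timing_convention`.
#' @export
timing_convention <- function(discount_rate = 0.03,
                              utilities = "cycle_start",
                              annual_costs = "cycle_start",
                              offsets = "cycle_start",
                              survival_weight_offsets = TRUE,
                              recovery_timing = c("immediate", "first_cycle_end")) {
  if (!is.numeric(discount_rate) || discount_rate < 0)
    stop_invalid("discount_rate", "must be >= 0")
  ok <- c("cycle_start", "half_cycle", "cycle_end")
  for (f in c("utilities", "annual_costs", "offsets")) {
    v <- get(f)
    if (!is.character(v) || length(v) != 1L || !v %in% ok)
      stop_invalid(f, paste("must be one of", paste(ok, collapse = ", ")))
  }
  structure(list(
    discount_rate = discount_rate,
    utilities = utilities,
    annual_costs = annual_costs,
    offsets = offsets,
    survival_weight_offsets = isTRUE(survival_weight_offsets),
    recovery_timing = match.arg(recovery_timing)),
    class = "timing_convention")
}

#' Discount factors for a stream
#'
#' @param cycles Zero-based cycle indices.
#' @param rate Annual discount rate.
#' @param timing Accrual timing (`"cycle_start"`, `"half_cycle"`,
#'   `"cycle_end"`).
#' @return Discount factors, one per cycle.
#' @export
discount_factors <- function(cycles, rate, timing = "cycle_start") {
  shift <- switch(timing,
                  cycle_start = 0,
                  half_cycle = 0.5,
                  cycle_end = 1,
                  stop_invalid("timing", "unknown accrual timing"))
  (1 + rate)^-(cycles + shift)
}

# ---- life table ----------------------------------------------------------

#' Read a life table from a two-column CSV
#'
#' The file must have columns `age` and `qx` (annual probability of death).
#' Ages between the tabulated knots are linearly interpolated; ages outside
#' the tabulated range take the nearest knot's value.
#'
#' @param path Path to the CSV file.
#' @return An object of class `life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table must have columns `age` and `qx`", call. = FALSE)
  if (any(df$qx < 0 | df$qx > 1)) stop_invalid("qx", "probabilities must be in [0, 1]")
  if (is.unsorted(df$age, strictly = TRUE)) df <- df[order(df$age), ]
  structure(list(age = df$age, qx = df$qx), class = "life_table")
}

#' Packaged synthetic life table
#'
#' A coarse, synthetic approximation of a contemporary US both-sex period
#' life table (annual mortality at 2- to 5-year age knots from 18 to 100),
#' packaged so the model runs without external data. At the model's 4- to
#' 8-year horizons results are insensitive to fine life-table detail.
#'
#' @return A `life_table` object.
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_synthetic.csv",
                              package = "discectomyCEA", mustWork = TRUE))
}

#' Annual natural mortality at a given age
#'
#' @param life_table A `life_table` object.
#' @param age Age in years (may be a vector).
#' @return Annual probability of death from natural causes.
#' @export
mortality_rate <- function(life_table, age) {
  stopifnot(inherits(life_table, "life_table"))
  stats::approx(life_table$age, life_table$qx, xout = age, rule = 2)$y
}

#' Zero-mortality life table
#'
#' Convenience constructor used for closed-form checks.
#'
#' @return A `life_table` with `qx = 0` at all ages.
#' @export
zero_life_table <- function() {
  structure(list(age = c(18, 100), qx = c(0, 0)), class = "life_table")
}

# ---- age distribution and productivity table -----------------------------

#' Age distribution of surgical patients
#'
#' Age-group shares of patients receiving discectomy, used to weight
#' per-cohort model results, with the representative start age of each band
#' (band midpoint; 35 for the under-40 group).
#'
#' @return A data frame with columns `age_group`, `weight`, `start_age`.
#' @export
surgical_age_distribution <- function() {
  data.frame(
    age_group = c("<40", "40-44", "45-49", "50-54", "55-59", "60-64"),
    weight = c(0.32, 0.15, 0.17, 0.15, 0.12, 0.09),
    start_age = c(35, 42, 47, 52, 57, 62),
    stringsAsFactors = FALSE)
}

#' Packaged productivity estimates by age group
#'
#' Published estimates of mean functional-limitations index scores (from the
#' SPORT cohorts), predicted annual household earnings, and the predicted
#' annual value of missed workdays (surgery recovery excluded) for surgical
#' and nonsurgical treatment, by age group. These are the fixture used by
#' the cost-effectiveness stage when it is run without survey microdata;
#' running the regression pipeline on the packaged synthetic-population
#' defaults reproduces the weighted-average row.
#'
#' @return A data frame, one row per age group, with score, earnings and
#'   missed-workday-value columns for each arm and their change
#'   (surgical minus nonsurgical for earnings; nonsurgical minus surgical,
#'   i.e. the saving, for missed-day values).
#' @export
productivity_table <- function() {
  df <- data.frame(
    age_group = c("<40", "40-44", "45-49", "50-54", "55-59", "60-64"),
    weight = c(0.32, 0.15, 0.17, 0.15, 0.12, 0.09),
    score_surgical = c(0.86, 0.85, 0.85, 0.87, 0.87, 0.86),
    score_nonsurgical = c(0.77, 0.75, 0.75, 0.74, 0.74, 0.76),
    earnings_surgical = c(44713, 50524, 49251, 48973, 48803, 46289),
    earnings_nonsurgical = c(42903, 48714, 47441, 46741, 46571, 44479),
    missed_value_surgical = c(1367, 1403, 1509, 1062, 1263, 1358),
    missed_value_nonsurgical = c(1869, 1917, 2063, 1561, 1857, 1855),
    stringsAsFactors = FALSE)
  df$earnings_change <- df$earnings_surgical - df$earnings_nonsurgical
  df$missed_value_change <- df$missed_value_nonsurgical - df$missed_value_surgical
  df
}

#' Published weighted-average productivity row
#'
#' The weighted-average row as published: the study applied the age weights
#' to its unrounded per-age estimates, so these values differ slightly
#' (e.g. weighted premium $1925) from re-weighting the rounded per-age rows
#' of [productivity_table()] (which gives $1923.9). Change columns are kept
#' identity-consistent with the per-arm cells.
#'
#' @return A one-row data frame with the same columns as
#'   [productivity_table()].
#' @export
productivity_table_weighted <- function() {
  df <- data.frame(
    age_group = "weighted", weight = 1,
    score_surgical = 0.86, score_nonsurgical = 0.76,
    earnings_surgical = 47619, earnings_nonsurgical = 45694,
    missed_value_surgical = 1337, missed_value_nonsurgical = 1859,
    stringsAsFactors = FALSE)
  df$earnings_change <- df$earnings_surgical - df$earnings_nonsurgical
  df$missed_value_change <- df$missed_value_nonsurgical - df$missed_value_surgical
  df
}

#' Weighted-average row of a productivity table
#'
#' Applies the age-group weights to every numeric column of a productivity
#' table (as returned by [productivity_table()] or
#' [predict_productivity()]).
#'
#' @param tab A productivity table with a `weight` column.
#' @return A one-row data frame of weighted means.
#' @export
weighted_productivity <- function(tab) {
  stopifnot(is.data.frame(tab), "weight" %in% names(tab))
  w <- tab$weight / sum(tab$weight)
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "weight"
  out <- as.data.frame(lapply(tab[num], function(col) sum(w * col)))
  cbind(data.frame(age_group = "weighted", weight = 1), out)
}
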