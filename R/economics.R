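# Cost-effectiveness arithmetic: present values of the productivity
# streams, incremental cost-effectiveness ratios with the net-cost identity
# D = A - B - C, and the time-horizon sweep.

#' Present value of an annual stream
#'
#' Sum of `annual_amount` times the discount factor of each cycle:
#' `cycle_end` gives the ordinary annuity `sum_{t=1..T} (1+r)^-t`,
#' `cycle_start` the annuity-due `sum_{t=0..T-1} (1+r)^-t`, and
#' `half_cycle` the mid-cycle convention.
#'
#' @param annual_amount Amount accruing each year.
#' @param horizon Number of years (>= 1).
#' @param rate Annual discount rate (> -1).
#' @param timing Accrual timing.
#' @return The present value.
#' @export
present_value_annuity <- function(annual_amount, horizon, rate = 0.03,
                                  timing = c("cycle_end", "cycle_start", "half_cycle")) {
  timing <- match.arg(timing)
  if (!is.numeric(rate) || rate <= -1) stop_invalid("rate", "must be > -1")
  if (!is.numeric(horizon) || horizon < 1) stop_invalid("horizon", "must be >= 1")
  annual_amount * sum(discount_factors(0:(as.integer(horizon) - 1L), rate, timing))
}

survival_pv <- function(annual_amount, survival, rate, timing) {
  sum(annual_amount * survival *
        discount_factors(seq_along(survival) - 1L, rate, timing))
}

#' Present value of the surgical earnings premium
#'
#' @param productivity [productivity_params()].
#' @param horizon Years of persisting benefit.
#' @param rate Annual discount rate.
#' @param survival Optional per-cycle survival fractions (surgical arm) by
#'   which the stream is weighted; length must equal `horizon`.
#' @param timing Accrual timing; defaults to the ordinary annuity when
#'   unweighted and to cycle-start accrual when survival-weighted.
#' @return Discounted earnings offset (USD).
#' @export
earnings_offset <- function(productivity, horizon, rate = 0.03, survival = NULL,
                            timing = if (is.null(survival)) "cycle_end" else "cycle_start") {
  stopifnot(inherits(productivity, "productivity_params"))
  if (is.null(survival))
    return(present_value_annuity(productivity$annual_earnings_premium, horizon, rate, timing))
  stopifnot(length(survival) == as.integer(horizon))
  survival_pv(productivity$annual_earnings_premium, survival, rate, timing)
}

#' Present value of the missed-workday effects (signed)
#'
#' The annual value of the missed-day reduction, minus the one-off cost of
#' the recovery absenteeism after the index operation
#' (`recovery_days * daily_wage`). Negative values mean the recovery
#' absenteeism dominates, i.e. missed workdays add to the cost of surgery.
#'
#' @inheritParams earnings_offset
#' @param daily_wage Wage used to value the recovery days; defaults to the
#'   baseline (nonsurgical) daily wage.
#' @param recovery_timing `"immediate"` values recovery days at surgery,
#'   undiscounted; `"first_cycle_end"` discounts them by one cycle.
#' @return Signed discounted offset (USD).
#' @export
missed_workday_offset <- function(productivity, horizon, rate = 0.03,
                                  daily_wage = productivity$baseline_daily_wage,
                                  survival = NULL,
                                  timing = if (is.null(survival)) "cycle_end" else "cycle_start",
                                  recovery_timing = c("immediate", "first_cycle_end")) {
  stopifnot(inherits(productivity, "productivity_params"))
  recovery_timing <- match.arg(recovery_timing)
  if (daily_wage < 0) stop_invalid("daily_wage", "must be >= 0")
  benefit <- if (is.null(survival)) {
    present_value_annuity(productivity$annual_missed_value_change, horizon, rate, timing)
  } else {
    stopifnot(length(survival) == as.integer(horizon))
    survival_pv(productivity$annual_missed_value_change, survival, rate, timing)
  }
  recovery <- productivity$recovery_days * daily_wage
  if (recovery_timing == "first_cycle_end") recovery <- recovery / (1 + rate)
  benefit - recovery
}

#' Incremental cost-effectiveness ratio of surgery vs nonsurgical care
#'
#' Combines the two arms' discounted totals with the productivity offsets
#' into the net-cost identity `D = A - B - C` and the ratio
#' `(D - F) / (E - G)`. With `include_productivity = FALSE` the offsets are
#' zeroed, giving the direct-medical-cost ICER. A non-positive incremental
#' QALY flags the ratio as undefined; a non-positive net incremental cost
#' with a QALY gain is reported as cost-saving (dominant), not as a
#' negative ratio.
#'
#' @param surgical,nonsurgical Arm results (`cohort_trace` or
#'   `arm_summary`) sharing the same horizon.
#' @param offsets List with elements `earnings` (B) and `missed_workdays`
#'   (C, signed).
#' @param include_productivity Include the offsets in the net cost?
#' @param setting Label for the surgery-cost setting.
#' @return An object of class `icer_result`.
#' @export
compute_icer <- function(surgical, nonsurgical,
                         offsets = list(earnings = 0, missed_workdays = 0),
                         include_productivity = TRUE,
                         setting = "overall") {
  if (!identical(surgical$horizon, nonsurgical$horizon))
    stop_invalid("horizon", "arms must share the same horizon")
  B <- if (include_productivity) offsets$earnings else 0
  C <- if (include_productivity) offsets$missed_workdays else 0
  A <- surgical$total_cost
  E <- surgical$total_qaly
  F_ <- nonsurgical$total_cost
  G <- nonsurgical$total_qaly
  D <- A - B - C
  dq <- E - G
  dc <- D - F_
  cost_saving <- dc <= 0 && dq > 0
  undefined <- dq <= 1e-12
  structure(list(
    setting = setting, horizon = surgical$horizon,
    include_productivity = include_productivity,
    direct_cost_surgical = A, earnings_offset = B, missed_workday_offset = C,
    net_cost_surgical = D, qaly_surgical = E,
    direct_cost_nonsurgical = F_, qaly_nonsurgical = G,
    incremental_cost = dc, incremental_qaly = dq,
    icer = if (cost_saving || undefined) NA_real_ else dc / dq,
    cost_saving = cost_saving, undefined = undefined,
    net_savings = if (cost_saving) -dc else 0), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> %s setting, %d-year horizon, productivity %s\n",
              x$setting, x$horizon,
              if (x$include_productivity) "included" else "excluded"))
  cat(sprintf("  surgical: cost $%.0f (net $%.0f), %.4f QALYs\n",
              x$direct_cost_surgical, x$net_cost_surgical, x$qaly_surgical))
  cat(sprintf("  nonsurgical: cost $%.0f, %.4f QALYs\n",
              x$direct_cost_nonsurgical, x$qaly_nonsurgical))
  if (x$undefined) {
    cat("  incremental QALY ~ 0: ICER undefined\n")
  } else if (x$cost_saving) {
    cat(sprintf("  dominant (cost-saving): net savings $%.0f, QALY gain %.4f\n",
                x$net_savings, x$incremental_qaly))
  } else {
    cat(sprintf("  ICER: $%.0f per QALY\n", x$icer))
  }
  invisible(x)
}

setting_surgery_cost <- function(costs, setting) {
  switch(setting,
         overall = costs$surgery_cost,
         inpatient = costs$surgery_cost_inpatient,
         outpatient = costs$surgery_cost_outpatient,
         stop_invalid("setting", "must be overall, inpatient or outpatient"))
}

#' Run the full cost-effectiveness analysis
#'
#' Runs both Markov arms for every age cohort in the configuration and
#' weights them by the surgical age distribution. The productivity offsets
#' are computed from the age-weighted productivity inputs (weighted annual
#' earnings premium, weighted missed-workday value change, weighted
#' baseline wage), accrued over the weighted surgical survival curve, and
#' the incremental cost-effectiveness result is returned.
#'
#' @param config A model configuration (see [default_config()]).
#' @param horizon_years Time horizon in years.
#' @param setting Surgery-cost setting: `"overall"` (blended),
#'   `"inpatient"` or `"outpatient"`.
#' @param include_productivity Include earnings/missed-workday offsets?
#' @return An `icer_result`; the per-age arm traces and the aggregated
#'   [productivity_params()] are attached as attributes `per_age` and
#'   `productivity`.
#' @export
run_cea <- function(config, horizon_years = 4, setting = "overall",
                    include_productivity = TRUE) {
  config <- validate_config(config)
  costs <- config$costs
  costs$surgery_cost <- setting_surgery_cost(costs, setting)
  ages <- config$ages
  tim <- config$timing
  run_one <- function(arm, a) {
    run_cohort(arm, config$clinical, config$utilities, costs,
               config$life_table, tim, a, horizon_years)
  }
  surg <- lapply(seq_len(nrow(ages)), function(i) run_one("surgical", ages$start_age[i]))
  nons <- lapply(seq_len(nrow(ages)), function(i) run_one("nonsurgical", ages$start_age[i]))
  names(surg) <- names(nons) <- ages$age_group
  s_all <- age_weighted_traces(surg, ages)
  n_all <- age_weighted_traces(nons, ages)
  # aggregate productivity inputs: the published weighted row when it is
  # available and the full age distribution is in play, otherwise the
  # weighted mean of the per-age inputs
  use_weighted <- !is.null(config$offsets_weighted) && nrow(ages) > 1 &&
    setequal(ages$age_group, config$offsets$age_group)
  if (use_weighted) {
    off <- config$offsets_weighted
    w <- 1
  } else {
    off <- merge(ages[c("age_group", "weight")], config$offsets, by = "age_group")
    w <- off$weight / sum(off$weight)
  }
  wage_ns <- sum(w * off$earnings_nonsurgical) / config$workdays_per_year
  pp <- productivity_params(
    annual_earnings_premium = sum(w * off$premium),
    annual_missed_value_change = sum(w * off$missed_value_change),
    annual_missed_day_reduction = sum(w * off$missed_value_change) / wage_ns,
    recovery_days = config$recovery_days,
    workdays_per_year = config$workdays_per_year,
    baseline_daily_wage = wage_ns)
  surv <- if (tim$survival_weight_offsets) s_all$alive else NULL
  offsets <- list(
    earnings = earnings_offset(pp, horizon_years, tim$discount_rate,
                               survival = surv, timing = tim$offsets),
    missed_workdays = missed_workday_offset(pp, horizon_years, tim$discount_rate,
                                            survival = surv, timing = tim$offsets,
                                            recovery_timing = tim$recovery_timing))
  res <- compute_icer(s_all, n_all, offsets, include_productivity, setting)
  attr(res, "per_age") <- list(surgical = surg, nonsurgical = nons)
  attr(res, "productivity") <- pp
  res
}

#' Sweep the time horizon of the analysis
#'
#' Re-runs the full analysis at each horizon and reports the ICER (with
#' productivity offsets), the net incremental cost, and the first horizon
#' at which surgery becomes cost-saving (net incremental cost <= 0),
#' attached as attribute `cost_saving_threshold`.
#'
#' @inheritParams run_cea
#' @param horizons Integer vector of horizons (years).
#' @return A data frame, one row per horizon.
#' @export
horizon_sweep <- function(config, horizons = 1:15, setting = "overall",
                          include_productivity = TRUE) {
  if (any(horizons < 1)) stop_invalid("horizons", "must be >= 1")
  rows <- lapply(horizons, function(h) {
    r <- run_cea(config, h, setting, include_productivity)
    data.frame(horizon = h, setting = setting,
               net_incremental_cost = r$incremental_cost,
               incremental_qaly = r$incremental_qaly,
               icer = r$icer, cost_saving = r$cost_saving)
  })
  out <- do.call(rbind, rows)
  thr <- out$horizon[out$net_incremental_cost <= 0]
  attr(out, "cost_saving_threshold") <- if (length(thr)) min(thr) else NA_integer_
  out
}
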