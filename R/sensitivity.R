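# One-way sensitivity analysis: re-run the 4-year pipeline with a single
# parameter moved to the ends of its tested range, everything else at base.

sens_setters <- function() {
  set_clin <- function(field) function(cfg, v) {
    args <- unclass(cfg$clinical); args[[field]] <- v
    cfg$clinical <- do.call(clinical_params, args); cfg
  }
  set_util <- function(field) function(cfg, v) {
    args <- unclass(cfg$utilities); args[[field]] <- v
    cfg$utilities <- do.call(utility_set, args); cfg
  }
  set_cost <- function(field) function(cfg, v) {
    args <- unclass(cfg$costs); args[[field]] <- v
    cfg$costs <- do.call(cost_params, args); cfg
  }
  list(
    revision_rate_year1 = set_clin("revision_rate_year1"),
    revision_rate_subsequent = set_clin("revision_rate_subsequent"),
    p_satisfactory_surgical = set_clin("p_satisfactory_surgical"),
    p_satisfactory_nonsurgical = set_clin("p_satisfactory_nonsurgical"),
    u_satisfactory = set_util("u_satisfactory"),
    u_unsatisfactory = set_util("u_unsatisfactory"),
    surgery_cost = set_cost("surgery_cost"),
    annual_medical_surgical = set_cost("annual_medical_surgical"),
    annual_medical_nonsurgical = set_cost("annual_medical_nonsurgical"),
    annual_earnings_premium = function(cfg, v) {
      cfg$offsets$premium <- rep(v, nrow(cfg$offsets))
      if (!is.null(cfg$offsets_weighted)) cfg$offsets_weighted$premium <- v
      cfg
    },
    annual_missed_day_reduction = function(cfg, v) {
      cfg$offsets$missed_value_change <-
        v * cfg$offsets$earnings_nonsurgical / cfg$workdays_per_year
      if (!is.null(cfg$offsets_weighted))
        cfg$offsets_weighted$missed_value_change <-
          v * cfg$offsets_weighted$earnings_nonsurgical / cfg$workdays_per_year
      cfg
    },
    recovery_days = function(cfg, v) {
      if (v < 0) stop_invalid("recovery_days", "must be >= 0")
      cfg$recovery_days <- v; cfg
    })
}

sens_getters <- function() {
  list(
    revision_rate_year1 = function(cfg) cfg$clinical$revision_rate_year1,
    revision_rate_subsequent = function(cfg) cfg$clinical$revision_rate_subsequent,
    p_satisfactory_surgical = function(cfg) cfg$clinical$p_satisfactory_surgical,
    p_satisfactory_nonsurgical = function(cfg) cfg$clinical$p_satisfactory_nonsurgical,
    u_satisfactory = function(cfg) cfg$utilities$u_satisfactory,
    u_unsatisfactory = function(cfg) cfg$utilities$u_unsatisfactory,
    surgery_cost = function(cfg) cfg$costs$surgery_cost,
    annual_medical_surgical = function(cfg) cfg$costs$annual_medical_surgical,
    annual_medical_nonsurgical = function(cfg) cfg$costs$annual_medical_nonsurgical,
    annual_earnings_premium = function(cfg) cfg$offsets$premium[1],
    annual_missed_day_reduction = function(cfg)
      cfg$offsets$missed_value_change[1] /
        (cfg$offsets$earnings_nonsurgical[1] / cfg$workdays_per_year),
    recovery_days = function(cfg) cfg$recovery_days)
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs the full 4-year analysis twice with the named parameter set to
#' `low` and to `high`, all other parameters at their base values, and
#' reports the resulting ICER pair alongside the base value.
#'
#' @param config Base configuration, typically [config_forty()].
#' @param param_name One of the parameter names listed by
#'   [sensitivity_parameters()].
#' @param low,high Tested parameter values.
#' @param horizon_years Horizon of the re-run (default 4).
#' @return A one-row data frame: `parameter`, `base`, `low`, `high`,
#'   `icer_low`, `icer_high`.
#' @export
one_way <- function(config, param_name, low, high, horizon_years = 4) {
  setters <- sens_setters()
  if (!param_name %in% names(setters))
    stop("unknown parameter `", param_name, "`; valid names: ",
         paste(names(setters), collapse = ", "), call. = FALSE)
  config <- validate_config(config)
  base <- sens_getters()[[param_name]](config)
  icer_at <- function(v) {
    run_cea(setters[[param_name]](config, v), horizon_years, "overall", TRUE)$icer
  }
  data.frame(parameter = param_name, base = base, low = low, high = high,
             icer_low = icer_at(low), icer_high = icer_at(high),
             stringsAsFactors = FALSE)
}

#' Names of parameters supported by the sensitivity analysis
#'
#' @return Character vector of valid `param_name` values for [one_way()].
#' @export
sensitivity_parameters <- function() names(sens_setters())

#' Full one-way sensitivity table
#'
#' Runs [one_way()] for every tabulated parameter over its published tested
#' range (at least +/-10% around base, or a literature/CI-based range) for
#' the 40-year-old base case.
#'
#' @param config Base configuration, default [config_forty()].
#' @return A data frame, one row per parameter.
#' @export
run_table5 <- function(config = config_forty()) {
  ranges <- list(
    revision_rate_year1 = c(0.04, 0.08),
    revision_rate_subsequent = c(0.01, 0.05),
    p_satisfactory_surgical = c(0.703, 0.803),
    p_satisfactory_nonsurgical = c(0.435, 0.535),
    u_satisfactory = c(0.80, 0.98),
    u_unsatisfactory = c(0.50, 0.62),
    annual_earnings_premium = c(1054, 2566),
    annual_missed_day_reduction = c(2.2, 3.4),
    surgery_cost = c(14781, 18065),
    annual_medical_surgical = c(2887, 3529),
    annual_medical_nonsurgical = c(3415, 4177),
    recovery_days = c(10, 30))
  rows <- Map(function(p, r) one_way(config, p, r[1], r[2]), names(ranges), ranges)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
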