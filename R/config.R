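# Configuration assembly, validation and end-to-end orchestration.

offset_inputs <- function(tab) {
  data.frame(
    age_group = tab$age_group,
    premium = tab$earnings_change,
    missed_value_change = tab$missed_value_change,
    earnings_nonsurgical = tab$earnings_nonsurgical,
    stringsAsFactors = FALSE)
}

#' Default model configuration
#'
#' Assembles the complete base-case configuration: clinical parameters,
#' utilities, direct costs, the calibrated accrual convention, the packaged
#' life table, the surgical age distribution, and the per-age productivity
#' offsets taken from `productivity` (defaults to the packaged
#' [productivity_table()]; pass a [predict_productivity()] result to use
#' regression-based offsets instead).
#'
#' When the packaged table is used, the aggregate (all-ages) analysis takes
#' its offset inputs from the published weighted-average row
#' ([productivity_table_weighted()]); for a user-supplied table the
#' weighted row is computed from the per-age rows.
#'
#' @param productivity A productivity table supplying per-age earnings and
#'   missed-workday values, or `NULL` for the packaged table.
#' @return A list of class `cea_config`.
#' @export
default_config <- function(productivity = NULL) {
  weighted <- if (is.null(productivity)) {
    productivity <- productivity_table()
    productivity_table_weighted()
  } else {
    weighted_productivity(productivity)
  }
  structure(list(
    clinical = clinical_params(),
    utilities = utility_set(),
    costs = cost_params(),
    timing = timing_convention(),
    life_table = default_life_table(),
    ages = surgical_age_distribution(),
    offsets = offset_inputs(productivity),
    offsets_weighted = offset_inputs(weighted),
    recovery_days = 20,
    workdays_per_year = 240), class = "cea_config")
}

#' Base configuration for the 40-year-old sensitivity case
#'
#' A single cohort starting at age 40 with the 40-44 age band's published
#' productivity inputs: annual earnings premium $1810 and an annual
#' missed-workday reduction of 2.7 days valued at the band's nonsurgical
#' daily wage.
#'
#' @return A `cea_config` for a single 40-year-old cohort.
#' @export
config_forty <- function() {
  cfg <- default_config()
  cfg$ages <- data.frame(age_group = "40-44", weight = 1, start_age = 40,
                         stringsAsFactors = FALSE)
  earn_ns <- 48714
  cfg$offsets <- data.frame(
    age_group = "40-44",
    premium = 1810,
    missed_value_change = 2.7 * earn_ns / cfg$workdays_per_year,
    earnings_nonsurgical = earn_ns,
    stringsAsFactors = FALSE)
  cfg$offsets_weighted <- NULL
  cfg
}

coerce_section <- function(raw, constructor, current) {
  if (is.null(raw)) return(current)
  if (inherits(current, "life_table")) stop("internal", call. = FALSE)
  args <- unclass(current)
  unknown <- setdiff(names(raw), names(args))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  args[names(raw)] <- raw
  do.call(constructor, args)
}

#' Validate (and complete) a model configuration
#'
#' Accepts a `cea_config`, a plain named list of overrides, or a path to a
#' YAML/JSON file of overrides. Missing sections and parameters default to
#' the published base case; every parameter is checked against its
#' invariants and violations are reported with the parameter name. An empty
#' file or list yields the fully defaulted configuration.
#'
#' @param raw Configuration object, override list or file path.
#' @return A validated `cea_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- if (grepl("\\.ya?ml$", raw)) {
      yaml::read_yaml(raw)
    } else if (grepl("\\.json$", raw)) {
      jsonlite::read_json(raw, simplifyVector = TRUE)
    } else stop("config file must be .yaml/.yml or .json", call. = FALSE)
    if (is.null(raw)) raw <- list()
  }
  if (inherits(raw, "cea_config")) {
    cfg <- raw
  } else {
    if (!is.list(raw)) stop_invalid("config", "must be a list or file path")
    cfg <- default_config()
    cfg$clinical <- coerce_section(raw$clinical, clinical_params, cfg$clinical)
    cfg$utilities <- coerce_section(raw$utilities, utility_set, cfg$utilities)
    cfg$costs <- coerce_section(raw$costs, cost_params, cfg$costs)
    cfg$timing <- coerce_section(raw$timing, timing_convention, cfg$timing)
    if (!is.null(raw$life_table)) {
      cfg$life_table <- if (is.character(raw$life_table))
        read_life_table(raw$life_table) else raw$life_table
    }
    for (f in c("ages", "offsets")) {
      if (!is.null(raw[[f]])) cfg[[f]] <- as.data.frame(raw[[f]])
    }
    for (f in c("recovery_days", "workdays_per_year")) {
      if (!is.null(raw[[f]])) cfg[[f]] <- check_nonneg(raw[[f]], f)
    }
  }
  # structural invariants
  stopifnot(inherits(cfg$clinical, "clinical_params"),
            inherits(cfg$utilities, "utility_set"),
            inherits(cfg$costs, "cost_params"),
            inherits(cfg$timing, "timing_convention"),
            inherits(cfg$life_table, "life_table"))
  if (abs(sum(cfg$ages$weight) - 1) > 1e-9)
    stop_invalid("ages", "weights must sum to 1")
  missing_off <- setdiff(cfg$ages$age_group, cfg$offsets$age_group)
  if (length(missing_off))
    stop_invalid("offsets", paste("no productivity inputs for age group(s):",
                                  paste(missing_off, collapse = ", ")))
  if (cfg$workdays_per_year <= 0) stop_invalid("workdays_per_year", "must be > 0")
  class(cfg) <- "cea_config"
  cfg
}

#' Run every stage of the analysis and write the result tables
#'
#' Orchestrates the pipeline end to end. In `"regression+cea"` mode a
#' synthetic worker population is generated (or `microdata` read from CSV),
#' the earnings and missed-days models are fitted, and the resulting
#' productivity predictions feed the cost-effectiveness stage; in
#' `"cea-only"` mode the packaged productivity table is used directly.
#' Writes `table3.csv` (productivity by age), `table4.csv` (costs, QALYs
#' and ICERs by setting and age cohort), `table5.csv` (one-way sensitivity),
#' `fig2_horizon.csv` (ICER by year of benefit and setting) and
#' `summary.json` to `out_dir`.
#'
#' @param config Configuration (see [validate_config()]).
#' @param out_dir Output directory, created if needed.
#' @param mode `"regression+cea"` or `"cea-only"`.
#' @param microdata Optional path to a worker-microdata CSV.
#' @param n Synthetic sample size when generating microdata.
#' @param seed Seed for the synthetic-population stage (the only stochastic
#'   stage; everything downstream is deterministic).
#' @return Invisibly, a list with all computed tables.
#' @export
run_all <- function(config = list(), out_dir, mode = c("regression+cea", "cea-only"),
                    microdata = NULL, n = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (mode == "regression+cea") {
    records <- if (is.null(microdata)) {
      generate_population(population_spec(n = n, seed = seed))
    } else read_microdata(microdata)
    em <- fit_earnings_model(records)
    dm <- fit_missed_days_model(records)
    table3 <- predict_productivity(em, dm)
    table3_weighted <- predict_productivity_weighted(em, dm)
    config$offsets <- offset_inputs(table3)
    config$offsets_weighted <- offset_inputs(table3_weighted)
  } else {
    table3 <- productivity_table()
    table3_weighted <- productivity_table_weighted()
  }
  keep <- intersect(names(productivity_table()), names(table3))
  table3_out <- rbind(table3[keep], table3_weighted[intersect(keep, names(table3_weighted))])

  icer_row <- function(r, label) {
    data.frame(cohort = label, setting = r$setting, horizon = r$horizon,
               direct_cost_surgical = r$direct_cost_surgical,
               earnings_offset = r$earnings_offset,
               missed_workday_offset = r$missed_workday_offset,
               net_cost_surgical = r$net_cost_surgical,
               qaly_surgical = r$qaly_surgical,
               direct_cost_nonsurgical = r$direct_cost_nonsurgical,
               qaly_nonsurgical = r$qaly_nonsurgical,
               icer = r$icer, cost_saving = r$cost_saving)
  }
  overall <- lapply(c("overall", "inpatient", "outpatient"), function(s)
    icer_row(run_cea(config, 4, s, TRUE), "overall"))
  per_age <- lapply(seq_len(nrow(config$ages)), function(i) {
    sub <- config
    sub$ages <- config$ages[i, ]
    sub$ages$weight <- 1
    icer_row(run_cea(sub, 4, "overall", TRUE), config$ages$age_group[i])
  })
  table4 <- do.call(rbind, c(overall, per_age))

  table5 <- run_table5(config_forty())

  fig2 <- do.call(rbind, lapply(c("overall", "inpatient", "outpatient"),
                                function(s) horizon_sweep(config, 1:15, s)))
  threshold <- function(s) {
    h <- fig2$horizon[fig2$setting == s & fig2$net_incremental_cost <= 0]
    if (length(h)) min(h) else NA_integer_
  }

  with_prod <- run_cea(config, 4, "overall", TRUE)
  without_prod <- run_cea(config, 4, "overall", FALSE)
  eight <- run_cea(config, 8, "overall", TRUE)
  summary <- list(
    horizon_years = 4,
    icer_with_productivity = with_prod$icer,
    icer_without_productivity = without_prod$icer,
    icer_8yr_with_productivity = eight$icer,
    incremental_qaly = with_prod$incremental_qaly,
    incremental_direct_cost = without_prod$incremental_cost,
    productivity_offset_total = with_prod$earnings_offset + with_prod$missed_workday_offset,
    cost_saving_threshold_years = list(
      overall = threshold("overall"),
      outpatient = threshold("outpatient"),
      inpatient = threshold("inpatient")),
    timing = unclass(config$timing),
    surgical_mortality = config$clinical$surgical_mortality,
    mode = mode, seed = seed)

  utils::write.csv(table3_out, file.path(out_dir, "table3.csv"), row.names = FALSE)
  utils::write.csv(table4, file.path(out_dir, "table4.csv"), row.names = FALSE)
  utils::write.csv(table5, file.path(out_dir, "table5.csv"), row.names = FALSE)
  utils::write.csv(fig2, file.path(out_dir, "fig2_horizon.csv"), row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table3 = table3_out, table4 = table4, table5 = table5,
                 fig2 = fig2, summary = summary))
}
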