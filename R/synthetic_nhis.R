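# Synthetic survey microdata with the statistical structure the
# productivity regressions assume: household earnings linear in a 0-1
# functional-limitations index (Gaussian noise, truncated at zero by
# resampling) and missed workdays negative-binomial (NB2) with a log link
# in the index and age group.

AGE_GROUPS <- c("<40", "40-44", "45-49", "50-54", "55-59", "60-64")
WORKDAY_CAP <- 240L

#' Specification of a synthetic worker population
#'
#' Defaults are calibrated so that fitting the earnings and missed-workday
#' models on a large generated sample and predicting at the packaged
#' functional-index scores reproduces the weighted-average row of
#' [productivity_table()]; see [calibrated_coefficients()].
#'
#' @param n Sample size.
#' @param age_weights Named fractions per age group, summing to 1.
#' @param earnings_coeffs List with `intercept` (USD), `score` (USD per unit
#'   index) and `age_offsets` (named, USD, first group 0).
#' @param earnings_noise_sd Residual standard deviation of earnings, USD.
#' @param missed_days_coeffs List with `intercept`, `score` and
#'   `age_offsets` on the log-link scale.
#' @param nb_dispersion NB2 dispersion `k > 0`
#'   (`variance = mu + mu^2 / k`).
#' @param score_mean,score_sd Mean and SD of the latent normal behind the
#'   functional-index distribution, truncated to `[0, 1]`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 1e5,
                            age_weights = NULL,
                            earnings_coeffs = NULL,
                            earnings_noise_sd = 10000,
                            missed_days_coeffs = NULL,
                            nb_dispersion = 1.5,
                            score_mean = 0.80,
                            score_sd = 0.25,
                            seed = 1L) {
  cal <- calibrated_coefficients()
  if (is.null(age_weights)) age_weights <- cal$age_weights
  if (is.null(earnings_coeffs)) earnings_coeffs <- cal$earnings
  if (is.null(missed_days_coeffs)) missed_days_coeffs <- cal$missed_days
  spec <- structure(list(
    n = n, age_weights = age_weights,
    earnings_coeffs = earnings_coeffs,
    earnings_noise_sd = earnings_noise_sd,
    missed_days_coeffs = missed_days_coeffs,
    nb_dispersion = nb_dispersion,
    score_mean = score_mean, score_sd = score_sd,
    seed = as.integer(seed)), class = "population_spec")
  validate_population_spec(spec)
}

validate_population_spec <- function(spec) {
  if (!is.numeric(spec$n) || length(spec$n) != 1L || is.na(spec$n) || spec$n < 1)
    stop_invalid("n", "must be a positive sample size")
  w <- spec$age_weights
  if (is.null(names(w)) || !setequal(names(w), AGE_GROUPS))
    stop_invalid("age_weights", "must be named with every age group")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop_invalid("age_weights", "must be non-negative and sum to 1")
  for (f in c("earnings_coeffs", "missed_days_coeffs")) {
    cf <- spec[[f]]
    if (!is.list(cf) || !all(c("intercept", "score", "age_offsets") %in% names(cf)))
      stop_invalid(f, "must list intercept, score and age_offsets")
    if (!setequal(names(cf$age_offsets), AGE_GROUPS))
      stop_invalid(f, "age_offsets must be named with every age group")
  }
  if (spec$earnings_noise_sd < 0) stop_invalid("earnings_noise_sd", "must be >= 0")
  if (!is.numeric(spec$nb_dispersion) || spec$nb_dispersion <= 0)
    stop_invalid("nb_dispersion", "must be > 0")
  if (spec$score_sd < 0) stop_invalid("score_sd", "must be >= 0")
  spec
}

#' Generator coefficients calibrated to the packaged productivity table
#'
#' Derives the default data-generating coefficients from
#' [productivity_table()]: the earnings slope equals the weighted earnings
#' change divided by the weighted functional-score change, with age offsets
#' absorbing the between-group earnings differences; the missed-days
#' log-link slope is set so that predicted days at the weighted surgical
#' and nonsurgical scores, valued at the predicted daily wage, reproduce the
#' table's weighted missed-workday values.
#'
#' @return A list with elements `age_weights`, `earnings`, `missed_days`,
#'   and `scores` (the weighted surgical/nonsurgical index scores).
#' @export
calibrated_coefficients <- function() {
  tab <- productivity_table()
  wrow <- weighted_productivity(tab)
  s_s <- 0.86  # printed weighted functional scores used for prediction
  s_ns <- 0.76
  beta <- wrow$earnings_change / (s_s - s_ns)
  intercept <- tab$earnings_surgical[1] - beta * tab$score_surgical[1]
  offsets <- tab$earnings_surgical - beta * tab$score_surgical - intercept
  names(offsets) <- tab$age_group
  # weighted earnings predictions at the printed scores
  base <- sum(tab$weight * (intercept + offsets))
  e_pred_s <- base + beta * s_s
  e_pred_ns <- base + beta * s_ns
  d_s <- wrow$missed_value_surgical / (e_pred_s / 240)
  d_ns <- wrow$missed_value_nonsurgical / (e_pred_ns / 240)
  slope_d <- (log(d_s) - log(d_ns)) / (s_s - s_ns)
  icpt_d <- log(d_s) - slope_d * s_s
  zero <- stats::setNames(numeric(length(AGE_GROUPS)), AGE_GROUPS)
  list(
    age_weights = stats::setNames(tab$weight, tab$age_group),
    earnings = list(intercept = intercept, score = beta, age_offsets = offsets),
    missed_days = list(intercept = icpt_d, score = slope_d, age_offsets = zero),
    scores = c(surgical = s_s, nonsurgical = s_ns))
}

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(max(mean, 0), 1), n))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic worker population
#'
#' Draws `spec$n` worker records: age group from `age_weights`, functional
#' score from a `[0, 1]`-truncated normal, household earnings from the
#' linear model with Gaussian noise (re-drawn while negative, so the linear
#' mean structure is preserved above zero), and missed workdays from an NB2
#' with log-link mean, capped at 240.
#'
#' @param spec A [population_spec()].
#' @return A data frame of worker records with columns `age_group`,
#'   `functional_score`, `household_earnings`, `missed_workdays`.
#' @export
generate_population <- function(spec) {
  spec <- validate_population_spec(spec)
  with_local_seed(spec$seed, {
    n <- as.integer(spec$n)
    groups <- sample(AGE_GROUPS, n, replace = TRUE, prob = spec$age_weights[AGE_GROUPS])
    score <- rtruncnorm01(n, spec$score_mean, spec$score_sd)
    ec <- spec$earnings_coeffs
    mu_e <- ec$intercept + ec$score * score + ec$age_offsets[groups]
    earnings <- stats::rnorm(n, mu_e, spec$earnings_noise_sd)
    while (any(bad <- earnings < 0))
      earnings[bad] <- stats::rnorm(sum(bad), mu_e[bad], spec$earnings_noise_sd)
    dc <- spec$missed_days_coeffs
    mu_d <- exp(dc$intercept + dc$score * score + dc$age_offsets[groups])
    days <- stats::rnbinom(n, mu = mu_d, size = spec$nb_dispersion)
    days <- pmin(days, WORKDAY_CAP)
    data.frame(
      age_group = factor(groups, levels = AGE_GROUPS),
      functional_score = score,
      household_earnings = as.numeric(earnings),
      missed_workdays = as.integer(days))
  })
}

validate_worker_records <- function(records, file = NULL) {
  where <- function(i) {
    if (is.null(file)) sprintf("record %d", i) else sprintf("%s: line %d", file, i + 1L)
  }
  req <- c("age_group", "functional_score", "household_earnings", "missed_workdays")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("microdata missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!(as.character(records$age_group) %in% AGE_GROUPS))
  if (length(bad)) stop(where(bad[1]), ": unknown age group", call. = FALSE)
  bad <- which(!is.finite(records$functional_score) |
                 records$functional_score < 0 | records$functional_score > 1)
  if (length(bad)) stop(where(bad[1]), ": functional_score outside [0, 1]", call. = FALSE)
  bad <- which(!is.finite(records$household_earnings) | records$household_earnings < 0)
  if (length(bad)) stop(where(bad[1]), ": negative household_earnings", call. = FALSE)
  bad <- which(!is.finite(records$missed_workdays) | records$missed_workdays < 0 |
                 records$missed_workdays > WORKDAY_CAP |
                 records$missed_workdays != round(records$missed_workdays))
  if (length(bad))
    stop(where(bad[1]), ": missed_workdays must be an integer in [0, ", WORKDAY_CAP, "]",
         call. = FALSE)
  invisible(records)
}

#' Write worker microdata to CSV
#'
#' Plain UTF-8 CSV with a header and deterministic row order; an empty
#' collection yields a header-only file.
#'
#' @param records Worker records as returned by [generate_population()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(records, path) {
  validate_worker_records(records)
  out <- records
  out$age_group <- as.character(out$age_group)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read worker microdata from CSV
#'
#' Validates every record against the worker-record invariants; a malformed
#' row raises an error naming the offending line.
#'
#' @param path CSV path written by [write_microdata()] or of the same layout.
#' @return A data frame of worker records.
#' @export
read_microdata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_worker_records(df, file = path)
  df$age_group <- factor(df$age_group, levels = AGE_GROUPS)
  df$missed_workdays <- as.integer(df$missed_workdays)
  df
}
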