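# Econometric stage: ordinary least squares for household earnings and an
# NB2 negative-binomial regression (maximum likelihood, log link) for
# missed workdays, both with the functional-limitations index and age group
# as predictors; prediction at fixed per-arm index scores yields the
# productivity table that feeds the cost-effectiveness stage.

# Drops age-group levels absent from the data so small or single-group
# samples stay full rank; unseen groups keep a zero offset in the fit.
prep_records <- function(records) {
  records$age_group <- droplevels(factor(records$age_group, levels = AGE_GROUPS))
  records
}

worker_formula <- function(records, response = "household_earnings") {
  rhs <- if (nlevels(records$age_group) > 1L) "functional_score + age_group"
         else "functional_score"
  stats::as.formula(paste(response, "~", rhs))
}

model_matrix_workers <- function(records) {
  stats::model.matrix(worker_formula(records), data = records)
}

#' Fit the household-earnings model by least squares
#'
#' Ordinary least squares of annual household earnings on the functional
#' score and age group (first group as reference).
#'
#' @param records Worker records (see [generate_population()]).
#' @return An object of class `earnings_model` with the intercept, score
#'   coefficient, per-age-group offsets, residual SD and the underlying
#'   `lm` fit.
#' @export
fit_earnings_model <- function(records) {
  validate_worker_records(records)
  records <- prep_records(records)
  if (length(unique(records$functional_score)) < 2L)
    stop("need at least 2 distinct functional scores", call. = FALSE)
  X <- model_matrix_workers(records)
  if (nrow(X) <= ncol(X))
    stop("more parameters than observations", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (singular fit)", call. = FALSE)
  fit <- stats::lm(worker_formula(records), data = records)
  cf <- stats::coef(fit)
  offsets <- stats::setNames(numeric(length(AGE_GROUPS)), AGE_GROUPS)
  seen <- sub("^age_group", "", grep("^age_group", names(cf), value = TRUE))
  offsets[seen] <- cf[paste0("age_group", seen)]
  structure(list(
    intercept = unname(cf["(Intercept)"]),
    score_coefficient = unname(cf["functional_score"]),
    age_offsets = offsets,
    residual_sd = stats::sigma(fit),
    fit = fit), class = "earnings_model")
}

nb2_negloglik <- function(par, X, y) {
  beta <- par[-length(par)]
  k <- exp(par[length(par)])
  mu <- exp(drop(X %*% beta))
  if (!all(is.finite(mu)) || !is.finite(k))
    return(.Machine$double.xmax / 2)  # off-scale trial point during line search
  nll <- -sum(suppressWarnings(stats::dnbinom(y, size = k, mu = mu, log = TRUE)))
  if (!is.finite(nll)) .Machine$double.xmax / 2 else nll
}

nb2_gradient <- function(par, X, y) {
  beta <- par[-length(par)]
  k <- exp(par[length(par)])
  mu <- exp(drop(X %*% beta))
  w <- (y - mu) * k / (k + mu)
  g_beta <- -drop(crossprod(X, w))
  dk <- sum(digamma(y + k) - digamma(k) + log(k) + 1 - log(k + mu) - (y + k) / (k + mu))
  c(g_beta, -k * dk)
}

#' Fit the missed-workdays model by NB2 maximum likelihood
#'
#' Negative-binomial (NB2, `variance = mu + mu^2 / k`) regression of annual
#' missed workdays on the functional score and age group, with a log link.
#' The likelihood is maximised directly (BFGS with analytic gradients,
#' initialised from a Poisson fit); the returned object records the
#' log-likelihood, a convergence flag and the score-coefficient standard
#' error from the observed information.
#'
#' @param records Worker records.
#' @param max_iter Maximum BFGS iterations.
#' @return An object of class `missed_days_model`.
#' @export
fit_missed_days_model <- function(records, max_iter = 500L) {
  validate_worker_records(records)
  records <- prep_records(records)
  y <- records$missed_workdays
  if (all(y == 0))
    stop("all counts are zero: a zero mean is not representable under the log link",
         call. = FALSE)
  X <- model_matrix_workers(records)
  if (nrow(X) <= ncol(X) + 1L)
    stop("more parameters than observations", call. = FALSE)
  pois <- stats::glm.fit(X, y, family = stats::poisson())
  # method-of-moments dispersion start keeps BFGS off the Poisson plateau
  mu0 <- pois$fitted.values
  excess <- sum((y - mu0)^2 - mu0)
  k0 <- if (excess > 0) max(min(sum(mu0^2) / excess, 1e4), 1e-2) else 1e4
  start <- c(pois$coefficients, log_k = log(k0))
  opt <- stats::optim(start, nb2_negloglik, nb2_gradient, X = X, y = y,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = max_iter, reltol = 1e-12))
  grad_norm <- sqrt(sum(nb2_gradient(opt$par, X, y)^2))
  if (opt$convergence != 0L)
    stop(sprintf("NB2 fit did not converge after %d iterations (gradient norm %.3g)",
                 max_iter, grad_norm), call. = FALSE)
  cf <- opt$par
  p <- ncol(X)
  vcov <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA_real_, p + 1, p + 1))
  offsets <- stats::setNames(numeric(length(AGE_GROUPS)), AGE_GROUPS)
  seen <- sub("^age_group", "", grep("^age_group", colnames(X), value = TRUE))
  offsets[seen] <- cf[paste0("age_group", seen)]
  structure(list(
    log_intercept = unname(cf["(Intercept)"]),
    score_coefficient = unname(cf["functional_score"]),
    age_offsets = offsets,
    dispersion = exp(unname(cf["log_k"])),
    log_lik = -opt$value,
    converged = TRUE,
    gradient_norm = grad_norm,
    score_se = sqrt(vcov[2, 2])), class = "missed_days_model")
}

predict_linear <- function(model, score, age_group, link = identity) {
  bad <- setdiff(unique(as.character(age_group)), AGE_GROUPS)
  if (length(bad))
    stop("unknown age group: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(score < 0 | score > 1))
    stop("functional scores must lie in [0, 1]", call. = FALSE)
  icpt <- if (inherits(model, "earnings_model")) model$intercept else model$log_intercept
  unname(link(icpt + model$score_coefficient * score +
                model$age_offsets[as.character(age_group)]))
}

#' Predict productivity outcomes at fixed functional scores
#'
#' Evaluates the fitted earnings and missed-days models at the surgical and
#' nonsurgical functional-index scores of each age group. A missed day is
#' valued at the arm's predicted annual earnings divided by
#' `workdays_per_year`.
#'
#' @param earnings_model An [fit_earnings_model()] result.
#' @param missed_days_model A [fit_missed_days_model()] result.
#' @param scores Data frame with columns `age_group`, `weight`,
#'   `score_surgical`, `score_nonsurgical`; defaults to the packaged
#'   per-age scores.
#' @param workdays_per_year Workdays in a full working year.
#' @return A productivity table (one row per age group) with predicted
#'   earnings, missed days and missed-day values per arm plus change
#'   columns; `earnings_change = surgical - nonsurgical`,
#'   `missed_value_change` and `missed_day_reduction` are the nonsurgical
#'   minus surgical saving.
#' @export
predict_productivity <- function(earnings_model, missed_days_model,
                                 scores = NULL, workdays_per_year = 240) {
  stopifnot(inherits(earnings_model, "earnings_model"),
            inherits(missed_days_model, "missed_days_model"))
  if (is.null(scores))
    scores <- productivity_table()[c("age_group", "weight",
                                     "score_surgical", "score_nonsurgical")]
  e_s <- predict_linear(earnings_model, scores$score_surgical, scores$age_group)
  e_ns <- predict_linear(earnings_model, scores$score_nonsurgical, scores$age_group)
  d_s <- predict_linear(missed_days_model, scores$score_surgical, scores$age_group, exp)
  d_ns <- predict_linear(missed_days_model, scores$score_nonsurgical, scores$age_group, exp)
  out <- data.frame(
    age_group = scores$age_group,
    weight = scores$weight,
    score_surgical = scores$score_surgical,
    score_nonsurgical = scores$score_nonsurgical,
    earnings_surgical = unname(e_s),
    earnings_nonsurgical = unname(e_ns),
    missed_days_surgical = unname(d_s),
    missed_days_nonsurgical = unname(d_ns),
    missed_value_surgical = unname(d_s * e_s / workdays_per_year),
    missed_value_nonsurgical = unname(d_ns * e_ns / workdays_per_year),
    stringsAsFactors = FALSE)
  out$earnings_change <- out$earnings_surgical - out$earnings_nonsurgical
  out$missed_day_reduction <- out$missed_days_nonsurgical - out$missed_days_surgical
  out$missed_value_change <- out$missed_value_nonsurgical - out$missed_value_surgical
  out
}

#' Predict the weighted-average productivity row
#'
#' Evaluates the fitted models at the age-weighted average functional
#' scores of each arm (rather than weighting per-age predictions made at
#' per-age scores), mirroring how the published weighted-average row is
#' constructed; the age mix enters through the age-group offsets.
#'
#' @inheritParams predict_productivity
#' @param score_surgical,score_nonsurgical Weighted-average functional
#'   scores of the two arms.
#' @param weights Age distribution used to average the age-group offsets;
#'   defaults to [surgical_age_distribution()].
#' @return A one-row productivity table labelled `"weighted"`.
#' @export
predict_productivity_weighted <- function(earnings_model, missed_days_model,
                                          score_surgical = 0.86,
                                          score_nonsurgical = 0.76,
                                          weights = NULL,
                                          workdays_per_year = 240) {
  if (is.null(weights)) weights <- surgical_age_distribution()
  scores <- data.frame(age_group = weights$age_group, weight = weights$weight,
                       score_surgical = score_surgical,
                       score_nonsurgical = score_nonsurgical)
  per_age <- predict_productivity(earnings_model, missed_days_model, scores,
                                  workdays_per_year)
  weighted_productivity(per_age)
}

#' Serialize fitted model coefficients to JSON
#'
#' @param model An `earnings_model` or `missed_days_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  keep <- setdiff(names(model), "fit")
  jsonlite::write_json(c(list(class = class(model)[1]), model[keep]), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
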