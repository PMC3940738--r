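# Annual-cycle Markov cohort engine. Health states are expanded by revision
# count to enforce the cap on repeat surgeries: Sat_r / Unsat_r for
# r = 0..max_revisions, a temporary Rev_r state per revision, and an
# absorbing Dead state. The nonsurgical arm only ever occupies Sat0, Unsat0
# and Dead.

markov_states <- function(max_revisions = 2L) {
  r <- seq_len(max_revisions)
  c(as.vector(rbind(paste0("Sat", 0:max_revisions), paste0("Unsat", 0:max_revisions))),
    if (max_revisions > 0L) paste0("Rev", r), "Dead")
}

state_utilities <- function(utilities, max_revisions = 2L) {
  st <- markov_states(max_revisions)
  u <- numeric(length(st))
  names(u) <- st
  u[grep("^Sat", st)] <- utilities$u_satisfactory
  u[grep("^Unsat", st)] <- utilities$u_unsatisfactory
  u[grep("^Rev", st)] <- utilities$u_revision
  u["Dead"] <- utilities$u_dead
  u
}

#' One-cycle transition matrix
#'
#' Builds the transition matrix applied between cycles `cycle_index - 1`
#' and `cycle_index`. The first cycle uses the first-year revision rate,
#' later cycles the subsequent-year rate. Within a cycle the event order is
#' natural death, then (surgical arm, outcome states below the revision
#' cap) relapse to revision surgery with its perioperative mortality, and
#' revision states resolve to an outcome state. The nonsurgical arm has no
#' revision pathway: its patients stay in their outcome state until death.
#'
#' @param params [clinical_params()].
#' @param life_table A `life_table` for natural mortality.
#' @param age Age (years) at the start of the cycle.
#' @param cycle_index 1-based cycle number.
#' @param arm `"surgical"` or `"nonsurgical"`.
#' @return A square transition matrix over [markov_states()]; every row
#'   sums to 1.
#' @export
build_transitions <- function(params, life_table, age, cycle_index,
                              arm = c("surgical", "nonsurgical")) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "clinical_params"))
  if (age < min(life_table$age) - 1e-9 || age > max(life_table$age) + 1e-9)
    stop_invalid("age", "outside the life-table domain")
  m <- params$max_revisions
  st <- markov_states(m)
  P <- matrix(0, length(st), length(st), dimnames = list(st, st))
  q <- mortality_rate(life_table, age)
  rr <- if (cycle_index <= 1L) params$revision_rate_year1 else params$revision_rate_subsequent
  mu <- params$surgical_mortality
  for (r in 0:m) {
    for (s in c(paste0("Sat", r), paste0("Unsat", r))) {
      P[s, "Dead"] <- q
      if (arm == "surgical" && r < m) {
        P[s, "Dead"] <- P[s, "Dead"] + (1 - q) * rr * mu
        P[s, paste0("Rev", r + 1)] <- (1 - q) * rr * (1 - mu)
        P[s, s] <- (1 - q) * (1 - rr)
      } else {
        P[s, s] <- 1 - q
      }
    }
    if (r >= 1) {
      rv <- paste0("Rev", r)
      P[rv, "Dead"] <- q
      P[rv, paste0("Sat", r)] <- (1 - q) * params$p_satisfactory_after_revision
      P[rv, paste0("Unsat", r)] <- (1 - q) * (1 - params$p_satisfactory_after_revision)
    }
  }
  P["Dead", "Dead"] <- 1
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12))
    stop("transition rows do not sum to 1 (inconsistent rates): ",
         paste(st[abs(rs - 1) > 1e-12], collapse = ", "), call. = FALSE)
  P
}

#' Initial state distribution after treatment allocation
#'
#' The surgical arm applies the per-operation mortality at the index
#' surgery, then the first-year revision risk (with a second mortality
#' exposure on entering revision), then splits the remaining mass into
#' satisfactory/unsatisfactory outcomes. The nonsurgical arm splits
#' directly by its satisfactory-outcome fraction.
#'
#' @inheritParams build_transitions
#' @return A named probability vector over [markov_states()].
#' @export
initial_state_distribution <- function(params, arm = c("surgical", "nonsurgical")) {
  arm <- match.arg(arm)
  st <- markov_states(params$max_revisions)
  occ <- stats::setNames(numeric(length(st)), st)
  if (arm == "nonsurgical") {
    occ["Sat0"] <- params$p_satisfactory_nonsurgical
    occ["Unsat0"] <- 1 - params$p_satisfactory_nonsurgical
    return(occ)
  }
  mu <- params$surgical_mortality
  alive <- 1 - mu
  rr <- if (params$max_revisions >= 1L) params$revision_rate_year1 else 0
  occ["Dead"] <- mu + alive * rr * mu
  if (params$max_revisions >= 1L) occ["Rev1"] <- alive * rr * (1 - mu)
  rest <- alive * (1 - rr)
  occ["Sat0"] <- rest * params$p_satisfactory_surgical
  occ["Unsat0"] <- rest * (1 - params$p_satisfactory_surgical)
  occ
}

#' Run one treatment arm of the Markov cohort model
#'
#' Simulates `horizon_years` annual cycles from the initial allocation,
#' accumulating discounted QALYs and discounted direct medical costs. Per
#' the accrual convention, utilities and annual costs accrue on the cycle's
#' state occupancy at the stream's discount timing; the index surgery cost
#' accrues at time zero undiscounted; each revision operation costs the
#' index surgery payment, charged on the revision-state occupancy of its
#' cycle.
#'
#' @param arm `"surgical"` or `"nonsurgical"`.
#' @param params [clinical_params()].
#' @param utilities [utility_set()].
#' @param costs [cost_params()]; `surgery_cost` is used for the index
#'   operation and revisions.
#' @param life_table A `life_table`.
#' @param timing [timing_convention()].
#' @param start_age Cohort age at treatment.
#' @param horizon_years Number of annual cycles (>= 1).
#' @return An object of class `cohort_trace`: the per-cycle occupancy and
#'   accumulator table plus arm totals.
#' @export
run_cohort <- function(arm, params, utilities, costs, life_table, timing,
                       start_age, horizon_years) {
  arm <- match.arg(arm, c("surgical", "nonsurgical"))
  stopifnot(inherits(utilities, "utility_set"), inherits(costs, "cost_params"),
            inherits(timing, "timing_convention"))
  if (!is.numeric(horizon_years) || length(horizon_years) != 1L || horizon_years < 1)
    stop_invalid("horizon_years", "must be >= 1")
  h <- as.integer(horizon_years)
  st <- markov_states(params$max_revisions)
  u <- state_utilities(utilities, params$max_revisions)
  annual_cost <- if (arm == "surgical") costs$annual_medical_surgical else costs$annual_medical_nonsurgical
  rate <- timing$discount_rate
  occ <- matrix(0, h, length(st), dimnames = list(NULL, st))
  occ[1, ] <- initial_state_distribution(params, arm)
  if (h > 1) for (t in 1:(h - 1)) {
    P <- build_transitions(params, life_table, start_age + t - 1, t + 1L, arm)
    occ[t + 1, ] <- occ[t, ] %*% P
  }
  cyc <- 0:(h - 1)
  df_u <- discount_factors(cyc, rate, timing$utilities)
  df_c <- discount_factors(cyc, rate, timing$annual_costs)
  alive <- 1 - occ[, "Dead"]
  rev_occ <- if (params$max_revisions > 0L)
    rowSums(occ[, grep("^Rev", st), drop = FALSE]) else numeric(h)
  qaly <- drop(occ %*% u) * df_u
  cost_annual <- annual_cost * alive * df_c
  cost_revision <- if (arm == "surgical") costs$surgery_cost * rev_occ * df_c else numeric(h)
  cost_surgery <- c(if (arm == "surgical") costs$surgery_cost else 0, numeric(h - 1))
  cost <- cost_annual + cost_revision + cost_surgery
  trace <- data.frame(cycle = cyc, occ, check.names = FALSE)
  trace$alive <- alive
  trace$qaly_disc <- qaly
  trace$cost_disc <- cost
  trace$cum_qaly <- cumsum(qaly)
  trace$cum_cost <- cumsum(cost)
  structure(list(
    trace = trace,
    total_qaly = sum(qaly),
    total_cost = sum(cost),
    alive = alive,
    arm = arm, start_age = start_age, horizon = h,
    timing = timing), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %s arm, start age %s, %d-year horizon\n",
              x$arm, format(x$start_age), x$horizon))
  cat(sprintf("  discounted QALYs: %.4f   discounted direct cost: $%.0f\n",
              x$total_qaly, x$total_cost))
  invisible(x)
}

#' Weight per-age arm results into an overall result
#'
#' @param per_age_results Named list of `cohort_trace` objects (or lists
#'   with `total_qaly`, `total_cost`, `alive`), one per age group.
#' @param age_distribution Data frame with `age_group` and `weight`
#'   columns; weights must sum to 1 and cover every listed result.
#' @return A list with weighted `total_qaly`, `total_cost` and `alive`
#'   (survival curve), of class `arm_summary`.
#' @export
age_weighted_traces <- function(per_age_results, age_distribution) {
  w <- stats::setNames(age_distribution$weight, age_distribution$age_group)
  if (abs(sum(w) - 1) > 1e-9)
    stop_invalid("age_distribution", "weights must sum to 1")
  missing_groups <- setdiff(names(w), names(per_age_results))
  if (length(missing_groups))
    stop("missing results for age group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  pick <- per_age_results[names(w)]
  structure(list(
    total_qaly = sum(w * vapply(pick, `[[`, numeric(1), "total_qaly")),
    total_cost = sum(w * vapply(pick, `[[`, numeric(1), "total_cost")),
    alive = Reduce(`+`, Map(function(wi, r) wi * r$alive, w, pick)),
    horizon = pick[[1]]$horizon), class = "arm_summary")
}
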