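# Independent oracles and small fixture builders.

# Exhaustive path-enumeration oracle for the cohort model, limited to
# max_revisions = 1. Walks every state path over the horizon, weighting by
# path probability, with its own transition arithmetic (no engine code).
# Accrual mirrors the model definition: utilities/annual costs at cycle
# start on occupancy, index surgery at t = 0 undiscounted, revision surgery
# charged on revision-state occupancy.
oracle_cohort <- function(arm, params, utilities, costs, qx, start_age,
                          horizon, rate = 0.03) {
  stopifnot(params$max_revisions == 1L)
  u_of <- function(s) switch(s,
    Sat0 = , Sat1 = utilities$u_satisfactory,
    Unsat0 = , Unsat1 = utilities$u_unsatisfactory,
    Rev1 = utilities$u_revision,
    Dead = 0)
  annual <- if (arm == "surgical") costs$annual_medical_surgical else costs$annual_medical_nonsurgical
  acc <- new.env()
  acc$qaly <- 0
  acc$cost <- if (arm == "surgical") costs$surgery_cost else 0
  visit <- function(state, t, prob) {
    df <- (1 + rate)^-t
    acc$qaly <- acc$qaly + prob * u_of(state) * df
    if (state != "Dead") acc$cost <- acc$cost + prob * annual * df
    if (state == "Rev1") acc$cost <- acc$cost + prob * costs$surgery_cost * df
    if (t == horizon - 1) return(invisible())
    q <- qx(start_age + t)
    mu <- params$surgical_mortality
    rr <- params$revision_rate_subsequent
    steps <- switch(state,
      Dead = list(c("Dead", 1)),
      Rev1 = list(c("Dead", q),
                  c("Sat1", (1 - q) * params$p_satisfactory_after_revision),
                  c("Unsat1", (1 - q) * (1 - params$p_satisfactory_after_revision))),
      Sat1 = list(c("Dead", q), c("Sat1", 1 - q)),
      Unsat1 = list(c("Dead", q), c("Unsat1", 1 - q)),
      Sat0 = if (arm == "surgical") {
        list(c("Dead", q + (1 - q) * rr * mu),
             c("Rev1", (1 - q) * rr * (1 - mu)),
             c("Sat0", (1 - q) * (1 - rr)))
      } else list(c("Dead", q), c("Sat0", 1 - q)),
      Unsat0 = if (arm == "surgical") {
        list(c("Dead", q + (1 - q) * rr * mu),
             c("Rev1", (1 - q) * rr * (1 - mu)),
             c("Unsat0", (1 - q) * (1 - rr)))
      } else list(c("Dead", q), c("Unsat0", 1 - q)))
    for (s in steps) {
      p2 <- as.numeric(s[2])
      if (p2 > 0) visit(s[1], t + 1, prob * p2)
    }
  }
  if (arm == "surgical") {
    mu <- params$surgical_mortality
    r1 <- params$revision_rate_year1
    alive <- 1 - mu
    init <- list(
      Dead = mu + alive * r1 * mu,
      Rev1 = alive * r1 * (1 - mu),
      Sat0 = alive * (1 - r1) * params$p_satisfactory_surgical,
      Unsat0 = alive * (1 - r1) * (1 - params$p_satisfactory_surgical))
  } else {
    init <- list(Sat0 = params$p_satisfactory_nonsurgical,
                 Unsat0 = 1 - params$p_satisfactory_nonsurgical)
  }
  for (s in names(init)) if (init[[s]] > 0) visit(s, 0, init[[s]])
  list(qaly = acc$qaly, cost = acc$cost)
}

flat_life_table <- function(q) {
  structure(list(age = c(18, 100), qx = c(q, q)), class = "life_table")
}

random_clinical_params <- function() {
  clinical_params(
    p_satisfactory_surgical = runif(1),
    p_satisfactory_nonsurgical = runif(1),
    p_satisfactory_after_revision = runif(1),
    revision_rate_year1 = runif(1, 0, 0.5),
    revision_rate_subsequent = runif(1, 0, 0.5),
    surgical_mortality = runif(1, 0, 0.1),
    max_revisions = sample(0:2, 1))
}

tiny_spec <- function(n = 200, seed = 1, noise_sd = 10000, ...) {
  population_spec(n = n, seed = seed, earnings_noise_sd = noise_sd, ...)
}
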