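# Small fully-synthetic parameter sets and net-benefit fixtures used across
# the test files. Everything is built in code; no external data.

# A minimal two-stratum, one-disease, two-intervention parameter set whose
# rates are all directly controllable. Defaults are degenerate (no events)
# so individual tests can switch on exactly the mechanism under test.
toy_params <- function(acm = 0, incidence = 0, prevalence = 0, excess = 0,
                       rr = c(1, 1, 1),
                       relapse = c(0, 0, 0),
                       discount = 0,
                       baseline_utility = 1, disease_utility = 1,
                       disease_cost = 0,
                       mean_age = 40L, horizon = 49L,
                       cohort_size = 1000L,
                       shares = c(0.5, 0.5),
                       n_strata = 2L,
                       adverse_events = list(
                         disutility_depression = 0, cost_depression = 0,
                         disutility_selfharm = 0, cost_selfharm = 0,
                         fatal_fraction_selfharm = 0),
                       course_costs = c(nrt_std = 0, test_tx = 0),
                       log_or_abstinence = c(nrt_std = 0, test_tx = 0),
                       log_or_mane = c(nrt_std = 0, test_tx = 0)) {
  ids <- c("male_35_64", "female_35_64")[seq_len(n_strata)]
  per <- function(x) stats::setNames(rep_len(x, n_strata), ids)
  strata <- data.frame(
    stratum_id = ids,
    sex = c("male", "female")[seq_len(n_strata)],
    age_band = rep("35-64", n_strata),
    cohort_share = rep_len(shares, n_strata) /
      sum(rep_len(shares, n_strata)) * sum(rep_len(shares, n_strata)),
    all_cause_mortality = rep_len(acm, n_strata),
    mean_age = rep(as.integer(mean_age), n_strata),
    stringsAsFactors = FALSE
  )
  strata$cohort_share <- rep_len(shares, n_strata)
  diseases <- list(COPD = list(
    disease_id = "COPD",
    incidence = per(incidence), prevalence = per(prevalence),
    excess_mortality = per(excess),
    rr_smoker = rr[1], rr_recent_quitter = rr[2], rr_long_quitter = rr[3],
    annual_cost = disease_cost, utility_value = disease_utility
  ))
  ivs <- data.frame(
    intervention_id = names(course_costs),
    licensed = TRUE,
    course_cost = unname(course_costs),
    stringsAsFactors = FALSE
  )
  cea_params(
    strata = strata, diseases = diseases,
    baseline_risks = list(p_abstain_nrt_std = 0.5,
                          p_depression_nrt_std = 0.07,
                          p_selfharm_nrt_std = 0.005),
    relapse = list(p_relapse_short = relapse[1], p_relapse_long = relapse[2],
                   p_relapse_10plus = relapse[3]),
    adverse_events = adverse_events,
    economics = list(discount_rate = discount, wtp = 20000,
                     population_per_year = 274021L,
                     cohort_size = as.integer(cohort_size),
                     psa_draws = 10L, horizon = as.integer(horizon),
                     baseline_utility = per(baseline_utility)),
    interventions = ivs,
    relative_effects = list(log_or_abstinence = log_or_abstinence,
                            log_or_mane = log_or_mane),
    harm_map = character(0),
    meta = list(standard_roster = FALSE)
  )
}

# A bare intervention profile (list), bypassing build_profiles so that
# degenerate probabilities (0 or 1) can be exercised.
toy_profile <- function(p_abstain = 0, p_depression = 0, p_selfharm = 0,
                        course_cost = 0, intervention_id = "test_tx") {
  list(intervention_id = intervention_id, licensed = TRUE,
       course_cost = course_cost, p_abstain = p_abstain,
       p_depression = p_depression, p_selfharm = p_selfharm)
}

# nb_matrix from explicit cost/qaly columns
toy_nb <- function(cost, qaly, ids = NULL) {
  cost <- as.matrix(cost); qaly <- as.matrix(qaly)
  if (is.null(ids)) ids <- paste0("tx", seq_len(ncol(cost)))
  colnames(cost) <- colnames(qaly) <- ids
  nb_matrix(cost, qaly)
}

# Brute-force dominance oracle: an option is dominated if beaten by a single
# alternative, extendedly dominated if beaten only by a convex combination
# of two alternatives. The mixing weight is searched over a grid plus the
# exact weights at which the mixture matches the candidate's cost or QALYs
# (the binding constraints), so the check is exact up to float precision.
oracle_frontier_status <- function(points, grid = seq(0, 1, by = 1e-3)) {
  n <- nrow(points)
  status <- character(n)
  beats <- function(c2, q2, c1, q1) {
    (c2 <= c1 + 1e-9 & q2 >= q1 - 1e-9) & (c2 < c1 - 1e-9 | q2 > q1 + 1e-9)
  }
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    simple <- any(beats(points$cost[others], points$qaly[others],
                        points$cost[i], points$qaly[i]))
    if (simple) { status[i] <- "dominated"; next }
    ext <- FALSE
    if (length(others) >= 2) {
      pairs <- utils::combn(others, 2)
      for (p in seq_len(ncol(pairs))) {
        j <- pairs[1, p]; k <- pairs[2, p]
        lam <- grid
        if (points$qaly[j] != points$qaly[k]) {
          lam <- c(lam, (points$qaly[i] - points$qaly[k]) /
                          (points$qaly[j] - points$qaly[k]))
        }
        if (points$cost[j] != points$cost[k]) {
          lam <- c(lam, (points$cost[i] - points$cost[k]) /
                          (points$cost[j] - points$cost[k]))
        }
        lam <- lam[lam >= 0 & lam <= 1]
        cm <- lam * points$cost[j] + (1 - lam) * points$cost[k]
        qm <- lam * points$qaly[j] + (1 - lam) * points$qaly[k]
        if (any(beats(cm, qm, points$cost[i], points$qaly[i]))) {
          ext <- TRUE
          break
        }
      }
    }
    status[i] <- if (ext) "extendedly_dominated" else "frontier"
  }
  stats::setNames(status, points$intervention_id)
}
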