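# Running the cohort model over PSA draws.
#
# After the quit-attempt cycle the cohort dynamics no longer depend on the
# intervention: every intervention's cohort is a mixture of the same two
# trajectories (a member who is a smoker at cycle 1 and one who is a
# quitter with counter 1), scaled by the surviving fraction, plus the
# one-off course cost and adverse-event terms. `run_psa()` therefore runs
# the engine twice per draw and assembles all interventions linearly; the
# result is identical (to numerical precision) to calling `run_cohort()`
# once per intervention.

# Per-member discounted (cost, qaly) from cycle 1 onward for a cohort whose
# members all start cycle 1 in the given smoking bin, distributed over
# strata and disease states as at model entry.
continuation_values <- function(ps, start_as = c("smoker", "quitter")) {
  start_as <- match.arg(start_as)
  trace <- build_initial_cohort(ps, keep_history = FALSE)
  if (start_as == "quitter") {
    occ <- trace$occ
    occ[2L, , ] <- occ[1L, , , drop = FALSE]
    occ[1L, , ] <- 0
    trace$occ <- occ
  }
  trace$cycle <- 1L
  acc <- accrue(trace, ps)
  trace <- record_cycle(trace, acc$cost, acc$qaly, acc$cost_disc,
                        acc$qaly_disc)
  cache <- new.env(parent = emptyenv())
  max_cycles <- ps$economics$horizon + 1L
  while (sum(trace$occ) > 1e-9 && trace$cycle < max_cycles) {
    trace <- transition(trace, ps, rate_cache = cache)
  }
  rows <- seq_len(trace$n_rows)
  n <- ps$economics$cohort_size
  c(cost = sum(trace$cycles[rows, "cost_disc"]) / n,
    qaly = sum(trace$cycles[rows, "qaly_disc"]) / n)
}

# Assemble per-intervention per-member totals from the two continuation
# values (see run_psa header note).
combine_profiles <- function(profiles, ps, v_smoke, v_quit) {
  ae <- ps$adverse_events
  r <- ps$economics$discount_rate
  disc1 <- (1 + r)^(-1)
  alive <- 1 - ae$fatal_fraction_selfharm * profiles$p_selfharm
  mix_cost <- profiles$p_abstain * v_quit["cost"] +
    (1 - profiles$p_abstain) * v_smoke["cost"]
  mix_qaly <- profiles$p_abstain * v_quit["qaly"] +
    (1 - profiles$p_abstain) * v_smoke["qaly"]
  one_off_cost <- profiles$course_cost +
    profiles$p_depression * ae$cost_depression +
    profiles$p_selfharm * (1 - ae$fatal_fraction_selfharm) * ae$cost_selfharm
  one_off_dis <- profiles$p_depression * ae$disutility_depression +
    profiles$p_selfharm * (1 - ae$fatal_fraction_selfharm) *
      ae$disutility_selfharm
  data.frame(
    intervention_id = profiles$intervention_id,
    cost_pp = alive * mix_cost + one_off_cost * disc1,
    qaly_pp = alive * mix_qaly - one_off_dis * disc1,
    stringsAsFactors = FALSE
  )
}

# Scenario adjustment of one parameter set: "base" keeps licensed
# interventions only; "no_adverse_events" zeroes the depression/self-harm
# probabilities and their one-off costs/disutilities so results are driven
# by abstinence alone.
apply_scenario <- function(ps, scenario) {
  if (scenario == "base") {
    keep <- ps$interventions$licensed
    ps$interventions <- ps$interventions[keep, , drop = FALSE]
  } else if (scenario == "no_adverse_events") {
    ps$baseline_risks$p_depression_nrt_std <- .Machine$double.eps
    ps$baseline_risks$p_selfharm_nrt_std <- .Machine$double.eps
    ps$adverse_events$disutility_depression <- 0
    ps$adverse_events$cost_depression <- 0
    ps$adverse_events$disutility_selfharm <- 0
    ps$adverse_events$cost_selfharm <- 0
    ps$adverse_events$fatal_fraction_selfharm <- 0
  }
  ps
}

#' Net-benefit matrix
#'
#' Container for draws x interventions cost and QALY matrices — the
#' substrate of all cost-effectiveness and value-of-information outputs.
#' Net benefit is always recomputed from cost and QALY at the requested
#' threshold, never stored.
#'
#' @param cost,qaly numeric matrices (draws x interventions) with aligned
#'   dimensions and identical column names.
#' @return an object of class `nb_matrix`.
#' @export
nb_matrix <- function(cost, qaly) {
  stopifnot(is.matrix(cost), is.matrix(qaly),
            identical(dim(cost), dim(qaly)),
            identical(colnames(cost), colnames(qaly)),
            !is.null(colnames(cost)))
  structure(list(cost = cost, qaly = qaly,
                 interventions = colnames(cost)),
            class = "nb_matrix")
}

#' @export
print.nb_matrix <- function(x, ...) {
  cat("<nb_matrix: ", nrow(x$cost), " draws x ", ncol(x$cost),
      " interventions>\n", sep = "")
  invisible(x)
}

#' Net benefit at a willingness-to-pay threshold
#'
#' @param m an [nb_matrix()].
#' @param wtp willingness to pay (GBP per QALY).
#' @return draws x interventions matrix of `qaly * wtp - cost`.
#' @export
net_benefit_draws <- function(m, wtp) {
  stopifnot(inherits(m, "nb_matrix"), is.numeric(wtp), wtp >= 0)
  m$qaly * wtp - m$cost
}

#' Run the cohort model over a PSA draw set
#'
#' For every draw: builds the intervention profiles from that draw's
#' relative-effect slice, runs the cohort engine, and records per-member
#' discounted lifetime cost and QALYs per intervention.
#'
#' @param draws a [sample_psa()] draw set (or a list of `cea_params`
#'   objects).
#' @param scenario `"all"` (14 interventions), `"base"` (licensed only) or
#'   `"no_adverse_events"` (all interventions, depression/self-harm
#'   removed).
#' @param progress_every print a progress line every this many draws
#'   (0 = silent).
#' @return an [nb_matrix()] with one row per draw.
#' @export
run_psa <- function(draws, scenario = c("all", "base", "no_adverse_events"),
                    progress_every = 0) {
  scenario <- match.arg(scenario)
  param_sets <- if (inherits(draws, "psa_draws")) draws$param_sets else draws
  n <- length(param_sets)
  stopifnot(n >= 1)

  first <- apply_scenario(param_sets[[1]], scenario)
  ids <- first$interventions$intervention_id
  cost <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  qaly <- cost

  for (i in seq_len(n)) {
    ps <- apply_scenario(param_sets[[i]], scenario)
    profiles <- build_profiles(ps$relative_effects, ps$baseline_risks,
                               ps$interventions, harm_map = ps$harm_map)
    if (scenario == "no_adverse_events") {
      profiles$p_depression <- 0
      profiles$p_selfharm <- 0
    }
    v_s <- continuation_values(ps, "smoker")
    v_q <- continuation_values(ps, "quitter")
    res <- combine_profiles(profiles, ps, v_s, v_q)
    cost[i, res$intervention_id] <- res$cost_pp
    qaly[i, res$intervention_id] <- res$qaly_pp
    if (progress_every > 0 && i %% progress_every == 0) {
      message("run_psa: draw ", i, "/", n)
    }
  }
  nb_matrix(cost, qaly)
}

#' Lifetime outcomes for every intervention under one parameter set
#'
#' Deterministic single-set counterpart of [run_psa()]: runs
#' [run_cohort()] once per intervention.
#'
#' @param ps a validated [cea_params()] object.
#' @param scenario see [run_psa()].
#' @return data.frame with `intervention_id`, `cost_pp`, `qaly_pp`.
#' @export
run_interventions <- function(ps,
                              scenario = c("all", "base",
                                           "no_adverse_events")) {
  scenario <- match.arg(scenario)
  ps <- apply_scenario(ps, scenario)
  profiles <- build_profiles(ps$relative_effects, ps$baseline_risks,
                             ps$interventions, harm_map = ps$harm_map)
  if (scenario == "no_adverse_events") {
    profiles$p_depression <- 0
    profiles$p_selfharm <- 0
  }
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    r <- run_cohort(profiles[i, ], ps)
    data.frame(intervention_id = profiles$intervention_id[i],
               cost_pp = r$cost_pp, qaly_pp = r$qaly_pp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
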