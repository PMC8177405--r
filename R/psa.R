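# Probabilistic sensitivity analysis: sampling complete parameter sets.
#
# Each sampled field is declared by a path string (e.g.
# "relapse.p_relapse_short", "diseases.COPD.annual_cost") with a dist_spec.
# Probabilities and utilities are Beta, costs Gamma, per-stratum
# epidemiology vectors are perturbed by a common lognormal multiplier
# (preserving the age/sex gradient within a draw), and relative effects come
# from the correlated log-OR draw matrices. Fields without a spec stay at
# their template values.

beta_spec_ess <- function(mean, ess) {
  dist_spec("beta", shape1 = mean * ess, shape2 = (1 - mean) * ess,
            anchor_mean = mean)
}

#' Default PSA distribution specs
#'
#' Builds the full mapping from sampled-field path to sampling distribution
#' for a parameter set: count-derived Beta distributions for the depression
#' and self-harm baselines (effective sample size 106,759, the source
#' cohort), an effective-sample-size-1000 Beta for the abstinence baseline,
#' interval-fitted Betas for the three relapse probabilities (0.13
#' (0.12-0.14), 0.03 (0.02-0.05), 0.0009 (0.0004-0.0015)), Gamma
#' distributions with 20% coefficient of variation for disease and
#' adverse-event costs (10% for course costs), Beta distributions for
#' utilities and disutilities, and lognormal multipliers (sdlog 0.1 for
#' incidence/excess mortality, 0.05 for all-cause mortality and risk
#' ratios). Any entry can be dropped or replaced to fix or re-specify a
#' field.
#'
#' @param ps template [cea_params()] object.
#' @return named list of [dist_spec()] objects keyed by field path.
#' @export
default_psa_specs <- function(ps) {
  specs <- list()
  br <- ps$baseline_risks
  specs[["baseline_risks.p_abstain_nrt_std"]] <-
    beta_spec_ess(br$p_abstain_nrt_std, 1000)
  specs[["baseline_risks.p_depression_nrt_std"]] <-
    beta_spec_ess(br$p_depression_nrt_std, 106759)
  specs[["baseline_risks.p_selfharm_nrt_std"]] <-
    beta_spec_ess(br$p_selfharm_nrt_std, 106759)

  relapse_ci <- list(
    p_relapse_short = c(0.12, 0.14),
    p_relapse_long = c(0.02, 0.05),
    p_relapse_10plus = c(0.0004, 0.0015)
  )
  for (f in names(relapse_ci)) {
    m <- ps$relapse[[f]]
    ci <- relapse_ci[[f]]
    specs[[paste0("relapse.", f)]] <-
      if (m >= ci[1] && m <= ci[2]) fit_beta_from_mean_ci(m, ci[1], ci[2])
      else beta_spec_ess(m, 500)
  }

  for (d in names(ps$diseases)) {
    dp <- ps$diseases[[d]]
    base <- paste0("diseases.", d, ".")
    specs[[paste0(base, "annual_cost")]] <-
      fit_gamma_from_mean_sd(dp$annual_cost, 0.2 * dp$annual_cost)
    specs[[paste0(base, "utility_value")]] <-
      fit_beta_from_mean_sd(dp$utility_value, 0.05)
    specs[[paste0(base, "incidence_mult")]] <-
      dist_spec("lognormal", meanlog = 0, sdlog = 0.1)
    specs[[paste0(base, "excess_mortality_mult")]] <-
      dist_spec("lognormal", meanlog = 0, sdlog = 0.1)
    for (rr in c("rr_smoker", "rr_recent_quitter", "rr_long_quitter")) {
      specs[[paste0(base, rr)]] <-
        dist_spec("lognormal", meanlog = log(dp[[rr]]) - 0.05^2 / 2,
                  sdlog = 0.05, anchor_mean = dp[[rr]])
    }
  }

  specs[["strata.all_cause_mortality_mult"]] <-
    dist_spec("lognormal", meanlog = 0, sdlog = 0.05)

  for (s in names(ps$economics$baseline_utility)) {
    specs[[paste0("economics.baseline_utility.", s)]] <-
      fit_beta_from_mean_sd(ps$economics$baseline_utility[[s]], 0.02)
  }

  ae <- ps$adverse_events
  specs[["adverse_events.cost_depression"]] <-
    fit_gamma_from_mean_sd(ae$cost_depression, 0.2 * ae$cost_depression)
  specs[["adverse_events.cost_selfharm"]] <-
    fit_gamma_from_mean_sd(ae$cost_selfharm, 0.2 * ae$cost_selfharm)
  specs[["adverse_events.disutility_depression"]] <-
    fit_beta_from_mean_sd(ae$disutility_depression, 0.05)
  specs[["adverse_events.disutility_selfharm"]] <-
    fit_beta_from_mean_sd(ae$disutility_selfharm, 0.05)
  specs[["adverse_events.fatal_fraction_selfharm"]] <-
    beta_spec_ess(ae$fatal_fraction_selfharm, 200)

  for (i in seq_len(nrow(ps$interventions))) {
    id <- ps$interventions$intervention_id[i]
    cc <- ps$interventions$course_cost[i]
    if (cc > 0) {
      specs[[paste0("interventions.course_cost.", id)]] <-
        fit_gamma_from_mean_sd(cc, 0.1 * cc)
    }
  }
  specs
}

# Apply one sampled value to a parameter set, dispatching on the path.
apply_sampled_value <- function(ps, path, value) {
  value <- unname(value)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  if (head %in% c("baseline_risks", "relapse", "adverse_events")) {
    ps[[head]][[parts[2]]] <- value
  } else if (head == "diseases") {
    d <- parts[2]; f <- parts[3]
    if (f == "incidence_mult") {
      ps$diseases[[d]]$incidence <- pmin(ps$diseases[[d]]$incidence * value, 1)
    } else if (f == "excess_mortality_mult") {
      ps$diseases[[d]]$excess_mortality <-
        pmin(ps$diseases[[d]]$excess_mortality * value, 1)
    } else {
      ps$diseases[[d]][[f]] <- value
    }
  } else if (head == "strata") {
    if (parts[2] == "all_cause_mortality_mult") {
      ps$strata$all_cause_mortality <-
        pmin(ps$strata$all_cause_mortality * value, 1)
    } else {
      stop("unknown strata field in spec path: ", path)
    }
  } else if (head == "economics") {
    if (parts[2] != "baseline_utility") {
      stop("unsupported economics field in spec path: ", path)
    }
    ps$economics$baseline_utility[[parts[3]]] <- value
  } else if (head == "interventions") {
    if (parts[2] != "course_cost") {
      stop("unsupported interventions field in spec path: ", path)
    }
    idx <- match(parts[3], ps$interventions$intervention_id)
    if (is.na(idx)) stop("unknown intervention in spec path: ", path)
    ps$interventions$course_cost[idx] <- value
  } else {
    stop("unknown spec path: ", path)
  }
  ps
}

#' Sample a probabilistic sensitivity analysis draw set
#'
#' Draws `n` complete parameter-set realizations: every field with an entry
#' in `specs` is sampled independently from its distribution, the
#' relative-effect slice comes from the aligned log-OR draw matrices, and
#' every other field is copied from the template. Identical
#' `(seed, n, specs)` yield bitwise-identical draw sets.
#'
#' @param ps_template a validated [cea_params()] object.
#' @param specs named list of [dist_spec()] objects keyed by field path;
#'   default [default_psa_specs()].
#' @param n number of draws (>= 1).
#' @param seed RNG seed.
#' @param re_draws optional `relative_effects_draws` with at least `n`
#'   draws; generated from the default anchors (seed `seed + 1`) when
#'   omitted.
#' @return an object of class `psa_draws`: list with `n_draws`, `seed`,
#'   `param_sets` (list of `cea_params`), `re_draws`, and `param_matrix`
#'   (draws x sampled-parameters numeric matrix, including the log-OR
#'   columns, used by the EVPPI metamodel).
#' @export
sample_psa <- function(ps_template, specs = default_psa_specs(ps_template),
                       n, seed = 1L, re_draws = NULL) {
  stopifnot(n >= 1)
  if (length(specs) == 0) stop("sample_psa: empty spec mapping")
  bad <- !vapply(specs, inherits, logical(1), what = "dist_spec")
  if (any(bad)) {
    stop("sample_psa: spec entries are not dist_spec objects: ",
         paste(names(specs)[bad], collapse = ", "))
  }

  paths <- sort(names(specs))
  set.seed(as.integer(seed))
  mat <- vapply(paths, function(p) spec_sample(specs[[p]], n), numeric(n))
  if (n == 1) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, paths))

  if (is.null(re_draws)) {
    re_draws <- generate_nma_draws(
      baseline_risks = ps_template$baseline_risks, n = n,
      seed = as.integer(seed) + 1L)
  }
  if (re_draws$n_draws < n) stop("re_draws has fewer draws than n")

  lor_cols <- function(block, prefix) {
    keep <- colnames(block)[colSums(is.na(block)) == 0 &
                              colnames(block) != "nrt_std"]
    m <- block[seq_len(n), keep, drop = FALSE]
    colnames(m) <- paste0(prefix, keep)
    m
  }
  param_matrix <- cbind(
    mat,
    lor_cols(re_draws$log_or_abstinence, "lor_abst."),
    lor_cols(re_draws$log_or_mane, "lor_mane.")
  )

  param_sets <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- ps_template
    for (p in paths) ps <- apply_sampled_value(ps, p, mat[i, p])
    ps$relative_effects <- re_slice(re_draws, i)
    ps$meta$draw_index <- i
    param_sets[[i]] <- ps
  }

  structure(
    list(n_draws = n, seed = as.integer(seed), param_sets = param_sets,
         re_draws = re_draws, param_matrix = param_matrix, specs = specs),
    class = "psa_draws"
  )
}

#' @export
print.psa_draws <- function(x, ...) {
  cat("<psa_draws: ", x$n_draws, " draws x ", ncol(x$param_matrix),
      " sampled parameters (seed ", x$seed, ")>\n", sep = "")
  invisible(x)
}
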