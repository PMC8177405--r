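#' @name quitcea-package
#' @aliases quitcea
#' @keywords internal
"_PACKAGE"

# Canonical identifiers ------------------------------------------------------

#' The intervention roster
#'
#' The fourteen smoking-cessation interventions compared by the model: seven
#' UK-licensed options (NRT, bupropion and varenicline at the doses shown),
#' two e-cigarette options and five combination therapies. NRT standard dose
#' is the baseline-risk reference intervention.
#'
#' @return a data.frame with columns `intervention_id`, `label` and
#'   `licensed`.
#' @export
cessation_roster <- function() {
  data.frame(
    intervention_id = c(
      "nrt_low", "nrt_std", "nrt_high",
      "bupropion_low", "bupropion_std",
      "varenicline_low", "varenicline_std",
      "ecig_low", "ecig_high",
      "bupropion_std_nrt_high", "varenicline_low_nrt_std",
      "varenicline_std_nrt_std", "varenicline_std_nrt_high",
      "varenicline_std_bupropion_std"
    ),
    label = c(
      "NRT low", "NRT standard", "NRT high",
      "Bupropion low", "Bupropion standard",
      "Varenicline low", "Varenicline standard",
      "E-cigarette low", "E-cigarette high",
      "Bupropion std + NRT high", "Varenicline low + NRT std",
      "Varenicline std + NRT std", "Varenicline std + NRT high",
      "Varenicline std + bupropion std"
    ),
    licensed = c(rep(TRUE, 7), rep(FALSE, 7)),
    stringsAsFactors = FALSE
  )
}

#' Disease identifiers
#' @return character vector of the five smoking-related chronic diseases the
#'   model tracks.
#' @export
disease_ids <- function() {
  c("COPD", "lung_cancer", "CHD", "stroke", "asthma")
}

#' Cohort stratum identifiers
#' @return character vector of the six sex-by-age-band strata.
#' @export
stratum_ids <- function() {
  c("male_18_34", "male_35_64", "male_65plus",
    "female_18_34", "female_35_64", "female_65plus")
}

age_band_levels <- function() c("18-34", "35-64", "65+")

# ParameterSet ---------------------------------------------------------------

#' Construct a parameter set
#'
#' Bundles every input the cohort model needs: cohort strata, disease
#' epidemiology, baseline risks on NRT standard, relapse probabilities,
#' adverse-event consequences, economic settings, intervention course costs
#' and one realized slice of the relative-effect draws. One `cea_params`
#' object is one internally consistent input set — either the deterministic
#' means or a single draw of the probabilistic sensitivity analysis.
#'
#' @param strata data.frame with columns `stratum_id`, `sex`, `age_band`,
#'   `cohort_share`, `all_cause_mortality`, `mean_age`.
#' @param diseases named list, one element per disease, each a list with
#'   per-stratum `incidence` (annual, never-smoker reference), `prevalence`,
#'   `excess_mortality` vectors and scalar `rr_smoker`,
#'   `rr_recent_quitter`, `rr_long_quitter`, `annual_cost`, `utility_value`.
#' @param baseline_risks list with `p_abstain_nrt_std`,
#'   `p_depression_nrt_std`, `p_selfharm_nrt_std`: one-year probabilities on
#'   the reference intervention.
#' @param relapse list with annual relapse probabilities `p_relapse_short`
#'   (years 1-5 since quitting), `p_relapse_long` (5-10 years),
#'   `p_relapse_10plus`.
#' @param adverse_events list with one-off `disutility_depression`,
#'   `cost_depression`, `disutility_selfharm`, `cost_selfharm` and
#'   `fatal_fraction_selfharm`.
#' @param economics list with `discount_rate`, `wtp`, `population_per_year`,
#'   `cohort_size`, `psa_draws`, `horizon` (maximum age) and per-stratum
#'   `baseline_utility`.
#' @param interventions data.frame with `intervention_id`, `licensed`,
#'   `course_cost`.
#' @param relative_effects list with named vectors `log_or_abstinence` and
#'   `log_or_mane` (log odds ratios versus NRT standard; `NA` marks
#'   interventions without direct neuropsychiatric evidence, resolved
#'   through the harm-assumption map).
#' @param harm_map named character vector mapping interventions without
#'   neuropsychiatric evidence to the donor intervention whose effect they
#'   borrow; defaults to [default_harm_map()].
#' @param meta optional list of free-form metadata (seed, generator version,
#'   `standard_roster` flag).
#' @return an object of class `cea_params`.
#' @seealso [validate_parameters()], [load_parameters()],
#'   [generate_default_parameters()]
#' @export
cea_params <- function(strata, diseases, baseline_risks, relapse,
                       adverse_events, economics, interventions,
                       relative_effects, harm_map = default_harm_map(),
                       meta = list()) {
  ps <- structure(
    list(
      strata = as.data.frame(strata, stringsAsFactors = FALSE),
      diseases = diseases,
      baseline_risks = baseline_risks,
      relapse = relapse,
      adverse_events = adverse_events,
      economics = economics,
      interventions = as.data.frame(interventions, stringsAsFactors = FALSE),
      relative_effects = relative_effects,
      harm_map = harm_map,
      meta = meta
    ),
    class = "cea_params"
  )
  ps
}

#' @export
print.cea_params <- function(x, ...) {
  cat("<cea_params>\n")
  cat("  strata:        ", nrow(x$strata), " (cohort size ",
      x$economics$cohort_size, ")\n", sep = "")
  cat("  diseases:      ", paste(names(x$diseases), collapse = ", "), "\n",
      sep = "")
  cat("  interventions: ", nrow(x$interventions), " (",
      sum(x$interventions$licensed), " licensed)\n", sep = "")
  cat("  discount rate: ", x$economics$discount_rate,
      ", WTP: £", format(x$economics$wtp, big.mark = ","), "/QALY\n",
      sep = "")
  v <- validate_parameters(x)
  cat("  validation:    ", if (nrow(v) == 0) "OK" else
    paste(nrow(v), "violation(s)"), "\n", sep = "")
  invisible(x)
}

# Validation -----------------------------------------------------------------

violation <- function(path, rule, value) {
  data.frame(path = path, rule = rule,
             value = paste(format(value), collapse = ","),
             stringsAsFactors = FALSE)
}

check_prob <- function(out, value, path, open = FALSE) {
  bad <- if (open) !is.finite(value) | value <= 0 | value >= 1
         else      !is.finite(value) | value < 0 | value > 1
  if (any(bad)) {
    out[[length(out) + 1L]] <- violation(
      path, if (open) "probability_in_open_unit_interval"
            else "probability_in_unit_interval", value[bad])
  }
  out
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a [cea_params()] object and reports
#' violations as data; it never raises. Rules include: cohort shares in
#' \[0, 1\] summing to one; all probabilities in \[0, 1\] (baseline risks
#' strictly inside (0, 1)); relapse probabilities weakly decreasing with
#' time since quitting; risk ratios positive; costs non-negative; utilities
#' in \[0, 1\]; per-stratum disease prevalences summing to at most one; the
#' reference intervention's log odds ratios identically zero; and aligned
#' rosters between the intervention table and the relative-effect slice.
#'
#' @param ps a [cea_params()] object.
#' @param strict_roster if `TRUE` (default when the set is flagged as
#'   carrying the standard roster), additionally require the fourteen
#'   interventions of [cessation_roster()].
#' @return a data.frame with columns `path`, `rule`, `value`; zero rows iff
#'   the set is valid.
#' @export
validate_parameters <- function(ps,
                                strict_roster =
                                  isTRUE(ps$meta$standard_roster)) {
  out <- list()
  st <- ps$strata
  ids <- st$stratum_id

  if (any(st$cohort_share < 0 | st$cohort_share > 1)) {
    out[[length(out) + 1L]] <- violation("strata.cohort_share",
                                         "share_in_unit_interval",
                                         st$cohort_share)
  }
  if (abs(sum(st$cohort_share) - 1) > 1e-8) {
    out[[length(out) + 1L]] <- violation("strata.cohort_share",
                                         "shares_sum_to_one",
                                         sum(st$cohort_share))
  }
  out <- check_prob(out, st$all_cause_mortality, "strata.all_cause_mortality")

  prev_sum <- stats::setNames(numeric(length(ids)), ids)
  for (d in names(ps$diseases)) {
    dp <- ps$diseases[[d]]
    base <- paste0("diseases.", d, ".")
    for (f in c("incidence", "prevalence", "excess_mortality")) {
      v <- unlist(dp[[f]])[ids]
      if (length(unlist(dp[[f]])) != length(ids) || any(is.na(v))) {
        out[[length(out) + 1L]] <- violation(paste0(base, f),
                                             "per_stratum_vector", NA)
        next
      }
      out <- check_prob(out, v, paste0(base, f))
    }
    prev_sum <- prev_sum + unlist(dp$prevalence)[ids]
    rrs <- c(dp$rr_smoker, dp$rr_recent_quitter, dp$rr_long_quitter)
    if (any(!is.finite(rrs) | rrs <= 0)) {
      out[[length(out) + 1L]] <- violation(paste0(base, "risk_ratios"),
                                           "risk_ratio_positive", rrs)
    }
    if (!is.finite(dp$annual_cost) || dp$annual_cost < 0) {
      out[[length(out) + 1L]] <- violation(paste0(base, "annual_cost"),
                                           "cost_nonnegative", dp$annual_cost)
    }
    out <- check_prob(out, dp$utility_value, paste0(base, "utility_value"))
  }
  if (any(is.na(prev_sum)) || any(prev_sum > 1 + 1e-8)) {
    out[[length(out) + 1L]] <- violation("diseases.*.prevalence",
                                         "prevalences_sum_at_most_one",
                                         prev_sum)
  }

  br <- ps$baseline_risks
  for (f in c("p_abstain_nrt_std", "p_depression_nrt_std",
              "p_selfharm_nrt_std")) {
    out <- check_prob(out, br[[f]], paste0("baseline_risks.", f), open = TRUE)
  }

  rl <- ps$relapse
  for (f in c("p_relapse_short", "p_relapse_long", "p_relapse_10plus")) {
    out <- check_prob(out, rl[[f]], paste0("relapse.", f))
  }
  if (!(rl$p_relapse_short >= rl$p_relapse_long &&
        rl$p_relapse_long >= rl$p_relapse_10plus)) {
    out[[length(out) + 1L]] <- violation(
      "relapse", "relapse_decreasing_with_time_since_quit",
      c(rl$p_relapse_short, rl$p_relapse_long, rl$p_relapse_10plus))
  }

  ae <- ps$adverse_events
  for (f in c("disutility_depression", "disutility_selfharm",
              "cost_depression", "cost_selfharm")) {
    if (!is.finite(ae[[f]]) || ae[[f]] < 0) {
      out[[length(out) + 1L]] <- violation(paste0("adverse_events.", f),
                                           "nonnegative", ae[[f]])
    }
  }
  out <- check_prob(out, ae$fatal_fraction_selfharm,
                    "adverse_events.fatal_fraction_selfharm")

  ec <- ps$economics
  if (!is.finite(ec$discount_rate) || ec$discount_rate < 0) {
    out[[length(out) + 1L]] <- violation("economics.discount_rate",
                                         "rate_nonnegative", ec$discount_rate)
  }
  if (!is.finite(ec$wtp) || ec$wtp <= 0) {
    out[[length(out) + 1L]] <- violation("economics.wtp", "wtp_positive",
                                         ec$wtp)
  }
  for (f in c("population_per_year", "cohort_size", "psa_draws", "horizon")) {
    v <- ec[[f]]
    if (!is.finite(v) || v <= 0 || abs(v - round(v)) > 1e-8) {
      out[[length(out) + 1L]] <- violation(paste0("economics.", f),
                                           "positive_integer", v)
    }
  }
  bu <- unlist(ec$baseline_utility)[ids]
  if (any(is.na(bu))) {
    out[[length(out) + 1L]] <- violation("economics.baseline_utility",
                                         "per_stratum_vector", NA)
  } else {
    out <- check_prob(out, bu, "economics.baseline_utility")
  }

  iv <- ps$interventions
  if (anyDuplicated(iv$intervention_id)) {
    out[[length(out) + 1L]] <- violation("interventions.intervention_id",
                                         "unique_ids", iv$intervention_id)
  }
  if (any(!is.finite(iv$course_cost) | iv$course_cost < 0)) {
    out[[length(out) + 1L]] <- violation("interventions.course_cost",
                                         "cost_nonnegative", iv$course_cost)
  }
  re <- ps$relative_effects
  for (f in c("log_or_abstinence", "log_or_mane")) {
    v <- re[[f]]
    if (!setequal(names(v), iv$intervention_id)) {
      out[[length(out) + 1L]] <- violation(paste0("relative_effects.", f),
                                           "roster_aligned", names(v))
    }
  }
  if ("nrt_std" %in% names(re$log_or_abstinence)) {
    ref <- c(re$log_or_abstinence[["nrt_std"]], re$log_or_mane[["nrt_std"]])
    if (any(is.na(ref)) || any(ref != 0)) {
      out[[length(out) + 1L]] <- violation("relative_effects.nrt_std",
                                           "reference_log_or_zero", ref)
    }
  }
  if (any(!is.finite(re$log_or_abstinence))) {
    out[[length(out) + 1L]] <- violation("relative_effects.log_or_abstinence",
                                         "finite", re$log_or_abstinence)
  }

  if (strict_roster &&
      !identical(sort(iv$intervention_id),
                 sort(cessation_roster()$intervention_id))) {
    out[[length(out) + 1L]] <- violation("interventions", "standard_roster",
                                         iv$intervention_id)
  }

  if (length(out) == 0) {
    data.frame(path = character(), rule = character(), value = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

# File I/O -------------------------------------------------------------------

required_top_fields <- function() {
  c("strata", "diseases", "baseline_risks", "relapse", "adverse_events",
    "economics", "interventions", "relative_effects")
}

#' Load a parameter file
#'
#' Reads a YAML parameter file (the schema written by [write_parameters()]),
#' checks that every required block is present — including all five disease
#' blocks — and that every invariant holds. Monetary values are GBP at 2019
#' prices; probabilities and rates are annual.
#'
#' @param path path to a YAML parameter file.
#' @return a validated [cea_params()] object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)

  missing <- setdiff(required_top_fields(), names(raw))
  if (length(missing)) {
    stop("parameter file schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  }
  missing_dis <- setdiff(disease_ids(), names(raw$diseases))
  if (length(missing_dis)) {
    stop("parameter file schema error: missing disease block(s) ",
         paste(missing_dis, collapse = ", "))
  }

  strata <- do.call(rbind, lapply(raw$strata, function(s) {
    data.frame(stratum_id = s$stratum_id, sex = s$sex, age_band = s$age_band,
               cohort_share = s$cohort_share,
               all_cause_mortality = s$all_cause_mortality,
               mean_age = s$mean_age, stringsAsFactors = FALSE)
  }))
  diseases <- lapply(raw$diseases, function(d) {
    d$incidence <- unlist(d$incidence)
    d$prevalence <- unlist(d$prevalence)
    d$excess_mortality <- unlist(d$excess_mortality)
    d
  })
  economics <- raw$economics
  economics$baseline_utility <- unlist(economics$baseline_utility)
  interventions <- do.call(rbind, lapply(raw$interventions, function(i) {
    data.frame(intervention_id = i$intervention_id, licensed = i$licensed,
               course_cost = i$course_cost, stringsAsFactors = FALSE)
  }))
  relative_effects <- list(
    log_or_abstinence = unlist(raw$relative_effects$log_or_abstinence),
    log_or_mane = vapply(raw$relative_effects$log_or_mane,
                         function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                         numeric(1))
  )
  harm_map <- if (is.null(raw$harm_map)) default_harm_map()
              else unlist(raw$harm_map)

  ps <- cea_params(
    strata = strata, diseases = diseases, baseline_risks = raw$baseline_risks,
    relapse = raw$relapse, adverse_events = raw$adverse_events,
    economics = economics, interventions = interventions,
    relative_effects = relative_effects, harm_map = harm_map,
    meta = raw$meta %||% list()
  )
  v <- validate_parameters(ps)
  if (nrow(v) > 0) {
    stop("parameter file failed validation:\n",
         paste(sprintf("  %s [%s] value=%s", v$path, v$rule, v$value),
               collapse = "\n"))
  }
  ps
}

#' Write a parameter set to a YAML file
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(ps, f))`
#' reproduces `ps` field for field (up to YAML's numeric precision, kept at
#' 15 significant digits).
#'
#' @param ps a [cea_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  raw <- list(
    meta = ps$meta,
    strata = lapply(seq_len(nrow(ps$strata)), function(i) as.list(ps$strata[i, ])),
    diseases = lapply(ps$diseases, function(d) {
      d$incidence <- as.list(d$incidence)
      d$prevalence <- as.list(d$prevalence)
      d$excess_mortality <- as.list(d$excess_mortality)
      d
    }),
    baseline_risks = ps$baseline_risks,
    relapse = ps$relapse,
    adverse_events = ps$adverse_events,
    economics = local({
      e <- ps$economics
      e$baseline_utility <- as.list(e$baseline_utility)
      e
    }),
    interventions = lapply(seq_len(nrow(ps$interventions)),
                           function(i) as.list(ps$interventions[i, ])),
    relative_effects = list(
      log_or_abstinence = as.list(ps$relative_effects$log_or_abstinence),
      log_or_mane = as.list(ps$relative_effects$log_or_mane)
    ),
    harm_map = as.list(ps$harm_map)
  )
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}
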