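# Mapping relative effects onto baseline risks.
#
# Relative effects are applied on the log-odds scale: the mapped probability
# is inv_logit(logit(p_base) + log OR). This is the standard scale for
# binary-outcome network meta-analysis and keeps every mapped probability
# inside (0, 1). A risk-ratio alternative is available for sensitivity
# analysis via `scale = "rr"` (with clamping at 1).

#' Apply a relative effect to a baseline probability
#'
#' @param p_base baseline probability, strictly inside (0, 1).
#' @param log_or finite log odds ratio (or log risk ratio when
#'   `scale = "rr"`).
#' @param scale `"or"` (default; logit-scale application, always returns a
#'   valid probability) or `"rr"` (risk-ratio application, clamped at 1).
#' @return the mapped probability; strictly increasing in `log_or`, and on
#'   the odds scale exactly invertible: applying `-log_or` recovers
#'   `p_base`.
#' @export
apply_relative_effect <- function(p_base, log_or, scale = c("or", "rr")) {
  scale <- match.arg(scale)
  if (any(!is.finite(p_base)) || any(p_base <= 0) || any(p_base >= 1)) {
    stop("apply_relative_effect: p_base must lie strictly inside (0, 1)")
  }
  if (any(!is.finite(log_or))) {
    stop("apply_relative_effect: log_or must be finite")
  }
  if (scale == "or") {
    inv_logit(logit(p_base) + log_or)
  } else {
    pmin(1 - .Machine$double.eps, p_base * exp(log_or))
  }
}

#' Resolve the MANE effect column for an intervention
#'
#' Interventions with direct neuropsychiatric evidence use their own log-OR
#' draws; those without borrow the donor column named in the
#' harm-assumption map, sharing the donor's draws (and hence its
#' correlation with every other column).
#'
#' @param intervention_id intervention to resolve.
#' @param log_or_mane named vector (one draw) or matrix (draws x
#'   interventions) of MANE log ORs, `NA` marking missing evidence.
#' @param harm_map named character vector mapping missing interventions to
#'   donors; default [default_harm_map()].
#' @return the resolved log-OR value(s) for the intervention.
#' @export
resolve_mane_column <- function(intervention_id, log_or_mane,
                                harm_map = default_harm_map()) {
  get_col <- function(id) {
    if (is.matrix(log_or_mane)) log_or_mane[, id] else log_or_mane[[id]]
  }
  ids <- if (is.matrix(log_or_mane)) colnames(log_or_mane) else names(log_or_mane)
  if (!intervention_id %in% ids) {
    stop("unknown intervention: ", intervention_id)
  }
  own <- get_col(intervention_id)
  if (!anyNA(own)) return(own)
  donor <- unname(harm_map[intervention_id])
  if (length(donor) != 1 || is.na(donor)) {
    stop("no MANE evidence and no harm-assumption donor for intervention '",
         intervention_id, "'")
  }
  if (!donor %in% ids) stop("harm-assumption donor '", donor,
                            "' not in roster")
  donor_col <- get_col(donor)
  if (anyNA(donor_col)) {
    stop("harm-assumption donor '", donor, "' has no observed MANE column")
  }
  donor_col
}

#' Build per-intervention one-year outcome profiles
#'
#' Turns one realized slice of the relative effects plus the NRT-standard
#' baseline risks into an intervention profile table: one-year probabilities
#' of sustained abstinence, depression and self-harm, and the one-off course
#' cost. A single MANE log OR drives both depression and self-harm, applied
#' separately to each baseline. The NRT-standard profile equals the
#' baselines exactly.
#'
#' @param relative_effects list with named vectors `log_or_abstinence` and
#'   `log_or_mane` (one draw).
#' @param baseline_risks baseline-risk list of a [cea_params()] object.
#' @param interventions intervention data.frame (`intervention_id`,
#'   `licensed`, `course_cost`).
#' @param harm_map named character vector; default [default_harm_map()].
#' @param scale effect-application scale, see [apply_relative_effect()].
#' @return data.frame of class `intervention_profiles` with columns
#'   `intervention_id`, `licensed`, `course_cost`, `p_abstain`,
#'   `p_depression`, `p_selfharm`.
#' @export
build_profiles <- function(relative_effects, baseline_risks, interventions,
                           harm_map = default_harm_map(),
                           scale = c("or", "rr")) {
  scale <- match.arg(scale)
  ids <- interventions$intervention_id
  lor_a <- relative_effects$log_or_abstinence
  if (!all(ids %in% names(lor_a))) {
    stop("build_profiles: abstinence effects missing for: ",
         paste(setdiff(ids, names(lor_a)), collapse = ", "))
  }
  mane <- vapply(ids, resolve_mane_column,
                 numeric(1), log_or_mane = relative_effects$log_or_mane,
                 harm_map = harm_map)
  out <- data.frame(
    intervention_id = ids,
    licensed = interventions$licensed,
    course_cost = interventions$course_cost,
    p_abstain = apply_relative_effect(baseline_risks$p_abstain_nrt_std,
                                      unname(lor_a[ids]), scale),
    p_depression = apply_relative_effect(baseline_risks$p_depression_nrt_std,
                                         unname(mane), scale),
    p_selfharm = apply_relative_effect(baseline_risks$p_selfharm_nrt_std,
                                       unname(mane), scale),
    stringsAsFactors = FALSE
  )
  class(out) <- c("intervention_profiles", "data.frame")
  out
}
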