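# Value-of-information analysis: EVPI and regression-based EVPPI.

#' Expected value of perfect information
#'
#' Per-person EVPI at a willingness-to-pay threshold: the mean over draws of
#' the best achievable net benefit minus the best expected net benefit,
#' i.e. `mean(max_i NB) - max_i mean(NB)`. Always non-negative.
#'
#' @param m an [nb_matrix()].
#' @param wtp willingness-to-pay threshold (GBP/QALY).
#' @return EVPI in GBP per person.
#' @export
evpi <- function(m, wtp) {
  stopifnot(inherits(m, "nb_matrix"))
  if (nrow(m$cost) < 2) stop("evpi: need at least 2 draws")
  nb <- net_benefit_draws(m, wtp)
  mean(matrixStats_rowMax(nb)) - max(colMeans(nb))
}

#' Population value of information
#'
#' Scales a per-person value to the population of quit attempts:
#' `per_person * population * years / 1e6`, undiscounted across years, in
#' GBP million.
#'
#' @param per_person per-person value (GBP).
#' @param population annual number of people affected by the decision
#'   (default 274,021 quit attempts per year in England).
#' @param years decision horizon in years.
#' @return population value in GBP million (unrounded).
#' @export
population_voi <- function(per_person, population = 274021L, years = 1) {
  stopifnot(per_person >= 0, population > 0, years > 0)
  per_person * population * years / 1e6
}

#' Expected value of partial perfect information (regression metamodel)
#'
#' Estimates EVPPI for a subset of model parameters by regressing each
#' intervention's net benefit on the subset with flexible smooths
#' (generalized additive model): for at most 4 parameters, one cubic
#' regression spline per parameter; for larger subsets the parameters are
#' first projected onto their leading principal components (default 4) and
#' the smooths fitted on those — a low-rank approximation in the spirit of
#' Gaussian-process metamodelling. EVPPI is then
#' `mean(max_i fitted_i) - max_i mean(fitted_i)`, clipped at zero.
#'
#' @param m an [nb_matrix()].
#' @param parameter_draws numeric matrix (draws x parameters), row-aligned
#'   with `m`.
#' @param wtp willingness-to-pay threshold.
#' @param max_smooth_dims number of smooth terms above which the
#'   principal-component projection is used (default 4).
#' @param basis_k basis dimension of each spline smooth (default 6).
#' @return EVPPI in GBP per person (non-negative). Returns 0 (with a
#'   message) if the subset carries no variation.
#' @export
evppi <- function(m, parameter_draws, wtp, max_smooth_dims = 4L,
                  basis_k = 6L) {
  stopifnot(inherits(m, "nb_matrix"))
  X <- as.matrix(parameter_draws)
  if (nrow(X) != nrow(m$cost)) {
    stop("evppi: parameter draws not row-aligned with the net-benefit matrix")
  }
  if (ncol(X) == 0) stop("evppi: empty parameter subset")
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 1e-12, drop = FALSE]
  if (ncol(X) == 0) {
    message("evppi: subset is constant across draws; EVPPI = 0")
    return(0)
  }
  if (ncol(X) > max_smooth_dims) {
    pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
    X <- pc$x[, seq_len(min(max_smooth_dims, ncol(pc$x))), drop = FALSE]
  }
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  nb <- net_benefit_draws(m, wtp)
  df <- as.data.frame(X)
  # basis dimension cannot exceed the number of distinct covariate values
  ks <- vapply(seq_len(ncol(X)), function(j) {
    min(basis_k, length(unique(X[, j])) - 1L)
  }, integer(1))
  # keep the metamodel identifiable: total coefficients (1 + sum(k - 1))
  # must stay below the number of draws; shrink the largest bases first and
  # drop to plain linear terms when draws are too few for any smooth
  n_draws <- nrow(X)
  while (1L + sum(pmax(ks, 1L) - 1L) >= n_draws && any(ks > 3L)) {
    ks[which.max(ks)] <- ks[which.max(ks)] - 1L
  }
  use_smooth <- ks >= 3L & (1L + sum(pmax(ks, 3L) - 1L)) < n_draws
  terms <- ifelse(use_smooth,
                  sprintf("s(x%d, bs = 'cr', k = %d)", seq_len(ncol(X)), ks),
                  sprintf("x%d", seq_len(ncol(X))))
  rhs <- paste(terms, collapse = " + ")
  fitted <- vapply(seq_len(ncol(nb)), function(i) {
    df$y <- nb[, i]
    if (stats::sd(df$y) < 1e-12) return(rep(mean(df$y), nrow(df)))
    fit <- mgcv::gam(stats::as.formula(paste("y ~", rhs)), data = df)
    as.numeric(stats::fitted(fit))
  }, numeric(nrow(nb)))
  max(0, mean(matrixStats_rowMax(fitted)) - max(colMeans(fitted)))
}

#' Default parameter subsets for the VoI report
#'
#' Maps the report's subset rows to column names of the PSA parameter
#' matrix. The two "head-to-head trial" rows restrict the net-benefit
#' matrix to NRT standard and varenicline standard (the two licensed
#' options with the highest expected net benefit) before computing EVPPI.
#'
#' @param param_cols column names of a [sample_psa()] `param_matrix`.
#' @return named list; each element has `cols` (character vector) and
#'   optionally `interventions` (restriction of the net-benefit matrix).
#' @export
default_voi_subsets <- function(param_cols) {
  grab <- function(...) {
    pat <- paste(c(...), collapse = "|")
    grep(pat, param_cols, value = TRUE)
  }
  cost_cols <- grab("annual_cost$", "^interventions\\.course_cost\\.",
                    "^adverse_events\\.cost_")
  util_cols <- grab("utility_value$", "^economics\\.baseline_utility\\.",
                    "^adverse_events\\.disutility_")
  abst_cols <- grab("^baseline_risks\\.p_abstain", "^lor_abst\\.")
  mane_cols <- grab("^baseline_risks\\.p_depression",
                    "^baseline_risks\\.p_selfharm", "^lor_mane\\.",
                    "^adverse_events\\.fatal_fraction")
  two <- c("nrt_std", "varenicline_std")
  two_prob <- intersect(c("baseline_risks.p_abstain_nrt_std",
                          "baseline_risks.p_depression_nrt_std",
                          "baseline_risks.p_selfharm_nrt_std",
                          "lor_abst.varenicline_std",
                          "lor_mane.varenicline_std"), param_cols)
  two_all <- intersect(c(two_prob,
                         paste0("interventions.course_cost.", two),
                         grab("^adverse_events\\.cost_",
                              "^adverse_events\\.disutility_")), param_cols)
  list(
    all = list(cols = param_cols),
    all_costs = list(cols = cost_cols),
    all_utilities = list(cols = util_cols),
    all_costs_and_utilities = list(cols = c(cost_cols, util_cols)),
    all_abstinence_probabilities = list(cols = abst_cols),
    all_depression_selfharm_probabilities = list(cols = mane_cols),
    nrt_std_vs_varenicline_std_prob_cost_util =
      list(cols = two_all, interventions = two),
    nrt_std_vs_varenicline_std_probabilities_only =
      list(cols = two_prob, interventions = two)
  )
}

restrict_nb <- function(m, interventions) {
  keep <- intersect(interventions, m$interventions)
  if (length(keep) < 2) {
    stop("cannot restrict net-benefit matrix: interventions missing (",
         paste(setdiff(interventions, m$interventions), collapse = ", "), ")")
  }
  nb_matrix(m$cost[, keep, drop = FALSE], m$qaly[, keep, drop = FALSE])
}

#' Value-of-information report
#'
#' Builds the full VoI table: per-person EVPI ("all" row) and EVPPI for the
#' named parameter subsets, each scaled to 1-year and 5-year population
#' values. EVPPI estimates are capped into `[0, EVPI]` (the theoretical
#' bounds; regression estimates can exceed EVPI by estimator noise).
#'
#' @param m an [nb_matrix()].
#' @param param_matrix draws x parameters matrix from [sample_psa()].
#' @param wtp willingness-to-pay threshold.
#' @param population annual quit attempts (default 274,021).
#' @param subsets named list as produced by [default_voi_subsets()].
#' @param ... passed on to [evppi()].
#' @return data.frame of class `voi_report` with columns `subset`,
#'   `evppi_pp`, `pop_1y_million`, `pop_5y_million`; the EVPI is row
#'   `"all"` and also stored in `attr(, "evpi_pp")`.
#' @export
voi_report <- function(m, param_matrix, wtp, population = 274021L,
                       subsets = default_voi_subsets(colnames(param_matrix)),
                       ...) {
  stopifnot(inherits(m, "nb_matrix"))
  ev <- evpi(m, wtp)
  rows <- lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    missing_cols <- setdiff(sub$cols, colnames(param_matrix))
    if (length(missing_cols)) {
      stop("voi_report: subset '", nm, "' references unknown parameters: ",
           paste(missing_cols, collapse = ", "))
    }
    if (nm == "all") {
      val <- ev
    } else {
      mm <- if (!is.null(sub$interventions)) {
        restrict_nb(m, sub$interventions)
      } else m
      val <- evppi(mm, param_matrix[, sub$cols, drop = FALSE], wtp, ...)
      val <- min(max(val, 0), ev)
    }
    data.frame(subset = nm, evppi_pp = val,
               pop_1y_million = population_voi(val, population, 1),
               pop_5y_million = population_voi(val, population, 5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "evpi_pp") <- ev
  attr(out, "wtp") <- wtp
  attr(out, "population") <- population
  class(out) <- c("voi_report", "data.frame")
  out
}
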