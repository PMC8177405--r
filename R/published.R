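# Published summary results of the UK smoking-cessation cost-effectiveness
# study the model re-implements. These are report-level outputs (probabilistic
# mean costs/QALYs and value-of-information figures), shipped as plain-text
# data so the package's frontier and population-scaling machinery can be
# exercised end-to-end against the printed numbers. They are inputs to those
# checks, not outputs of this package's model.

#' Published mean lifetime costs and QALYs (all-interventions analysis)
#'
#' Per-smoker expected total discounted cost (GBP) and QALYs for the
#' fourteen interventions, as reported by the published UK analysis across
#' 5,000 Monte Carlo simulations. Feeding this table to
#' [efficiency_frontier()] reproduces the published dominance structure:
#' only NRT low and e-cigarette low on the frontier, the twelve others
#' dominated, and an ICER of about £56/QALY for e-cigarette low versus NRT
#' low.
#'
#' @return data.frame with `intervention_id`, `cost`, `qaly`.
#' @export
published_cea_means <- function() {
  utils::read.csv(system.file("extdata", "published_cea_means.csv",
                              package = "quitcea"),
                  stringsAsFactors = FALSE)
}

#' Published value-of-information figures
#'
#' Per-quitter EVPI/EVPPI (GBP) and 1-/5-year population values (GBP
#' million, population 274,021 quit attempts per year) for the base-case
#' analysis at £20,000/QALY, by parameter subset.
#'
#' @return data.frame with `subset`, `evppi_pp`, `pop_1y_million`,
#'   `pop_5y_million`.
#' @export
published_voi <- function() {
  utils::read.csv(system.file("extdata", "published_voi.csv",
                              package = "quitcea"),
                  stringsAsFactors = FALSE)
}

#' Published baseline event counts on NRT standard
#'
#' Source-cohort counts behind the baseline risks: 8,274 of 106,759 NRT
#' users reported depression and 540 of 106,759 reported self-harm within
#' one year; one-year sustained abstinence on NRT was reported as 21.2%.
#'
#' @return list with `depression` and `selfharm` (each `c(events, n)`) and
#'   `abstinence_probability`.
#' @export
published_baseline_counts <- function() {
  list(depression = c(events = 8274, n = 106759),
       selfharm = c(events = 540, n = 106759),
       abstinence_probability = 0.212)
}
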