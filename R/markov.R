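# Markov cohort engine.
#
# Deterministic expected-value cohort arithmetic (no microsimulation) on the
# state space
#   stratum (sex x age band at entry)
#     x smoking status (smoker | quitter with years-since-quit counter)
#     x disease (none | COPD | lung cancer | CHD | stroke | asthma),
# with dead absorbing. Cycle length is one year (all input rates are
# annual); no half-cycle correction. Quitter counters are tracked as twelve
# bins: bin 1 = smoker, bins 2-11 = counters 1-10, bin 12 = counter >= 11.
# Counters drive both relapse (short-run < 5 years, long-run 5-10, >= 10)
# and the smoking-status risk ratios (recent quitter < 5 years, long-term
# >= 5). Disease states are mutually exclusive first-event states. Members
# age one year per cycle and adopt the next age band's rates when they cross
# a band boundary; everyone still alive after the cycle in which they reach
# the maximum age (default 100) is removed from the model.

N_BINS <- 12L

# bin -> relapse class and risk-ratio status
bin_relapse_class <- function() {
  # 1 smoker (no relapse), 2-5 counters 1-4 (short), 6-10 counters 5-9
  # (long), 11-12 counters 10+ (10plus)
  c("none", rep("short", 4), rep("long", 5), rep("10plus", 2))
}
bin_status <- function() {
  c("smoker", rep("recent", 4), rep("long", 7))
}

band_of_age <- function(age) {
  age_band_levels()[findInterval(age, c(0, 35, 65))]
}

# Row index of the strata table supplying rates for each entry stratum at
# its current age; falls back to the entry row when the (sex, band) pair is
# absent (toy parameter sets).
rate_rows <- function(strata, age) {
  band <- band_of_age(age)
  key <- paste(strata$sex, strata$age_band)
  j <- match(paste(strata$sex, band), key)
  own <- seq_len(nrow(strata))
  j[is.na(j)] <- own[is.na(j)]
  as.integer(j)
}

# Per-cycle rate arrays for one (sex, band) configuration j. Cached by the
# caller: configurations change only when a stratum crosses a band boundary.
make_cycle_rates <- function(ps, j) {
  st <- ps$strata
  n_s <- nrow(st)
  dis <- ps$diseases
  n_d <- length(dis)
  rid <- st$stratum_id[j]
  status <- bin_status()

  # risk ratio by (bin, disease)
  rr_bin <- vapply(dis, function(d) {
    unname(c(smoker = d$rr_smoker, recent = d$rr_recent_quitter,
             long = d$rr_long_quitter)[status])
  }, numeric(N_BINS))                                   # 12 x n_d

  inc_base <- vapply(dis, function(d) unname(d$incidence[rid]), numeric(n_s))
  inc_base <- matrix(inc_base, n_s, n_d)                # n_s x n_d
  exc_base <- vapply(dis, function(d) unname(d$excess_mortality[rid]),
                     numeric(n_s))
  exc_base <- matrix(exc_base, n_s, n_d)

  n_clamped <- 0L
  # incidence array (bin, disease, stratum), clamped per disease then scaled
  # so the total acquisition probability never exceeds 1
  p_inc <- array(rep(rr_bin, times = n_s), c(N_BINS, n_d, n_s)) *
    array(rep(t(inc_base), each = N_BINS), c(N_BINS, n_d, n_s))
  over <- p_inc > 1
  n_clamped <- n_clamped + sum(over)
  p_inc[over] <- 1
  tot <- apply(p_inc, c(1, 3), sum)                     # 12 x n_s
  over_tot <- tot > 1
  if (any(over_tot)) {
    n_clamped <- n_clamped + sum(over_tot)
    scale <- ifelse(over_tot, 1 / tot, 1)               # 12 x n_s
    sc_arr <- array(0, c(N_BINS, n_d, n_s))
    for (d in seq_len(n_d)) sc_arr[, d, ] <- scale
    p_inc <- p_inc * sc_arr
    tot <- pmin(tot, 1)
  }

  acm <- st$all_cause_mortality[j]                      # length n_s
  # death array (bin, 1 + n_d, stratum)
  p_die <- array(0, c(N_BINS, 1L + n_d, n_s))
  p_die[, 1L, ] <- matrix(acm, N_BINS, n_s, byrow = TRUE)
  for (d in seq_len(n_d)) {
    pd <- outer(rr_bin[, d], exc_base[, d]) +
      matrix(acm, N_BINS, n_s, byrow = TRUE)
    ov <- pd > 1
    n_clamped <- n_clamped + sum(ov)
    pd[ov] <- 1
    p_die[, 1L + d, ] <- pd
  }

  bu <- unlist(ps$economics$baseline_utility)[rid]      # length n_s
  util <- vapply(dis, function(d) d$utility_value, numeric(1))
  cost <- vapply(dis, function(d) d$annual_cost, numeric(1))

  # precomputed accrual arrays (bin, disease, stratum) and (bin, stratum)
  cost_arr <- array(rep(cost, each = N_BINS), c(N_BINS, n_d, n_s))
  util_arr <- array(rep(util, each = N_BINS), c(N_BINS, n_d, n_s))
  bu_mat <- matrix(bu, N_BINS, n_s, byrow = TRUE)

  list(p_inc = p_inc, p_inc_tot = tot, p_die = p_die, bu = bu,
       util = util, cost = cost, cost_arr = cost_arr, util_arr = util_arr,
       bu_mat = bu_mat, n_clamped = n_clamped)
}

# memoized lookup of the rate arrays for the band configuration at `age`
get_rates <- function(ps, age, rate_cache = NULL) {
  j <- rate_rows(ps$strata, age)
  key <- paste(j, collapse = ",")
  if (!is.null(rate_cache)) {
    r <- rate_cache[[key]]
    if (!is.null(r)) return(r)
  }
  r <- make_cycle_rates(ps, j)
  if (!is.null(rate_cache)) rate_cache[[key]] <- r
  r
}

new_trace <- function(occ, dead, cycle, age, ps, keep_history = TRUE) {
  max_rows <- ps$economics$horizon + 2L
  cyc <- matrix(NA_real_, max_rows, 7L,
                dimnames = list(NULL, c("cycle", "cost", "qaly", "cost_disc",
                                        "qaly_disc", "dead_cum", "alive")))
  structure(
    list(
      occ = occ, dead = dead, cycle = cycle, age = age,
      cycles = cyc, n_rows = 0L,
      occ_history = if (keep_history) list() else NULL,
      n_clamped = 0L,
      dims = list(strata = ps$strata$stratum_id,
                  diseases = names(ps$diseases))
    ),
    class = "cohort_trace"
  )
}

record_cycle <- function(trace, cost, qaly, cost_disc, qaly_disc) {
  i <- trace$n_rows + 1L
  trace$n_rows <- i
  trace$cycles[i, ] <- c(trace$cycle, cost, qaly, cost_disc, qaly_disc,
                         trace$dead, sum(trace$occ))
  if (!is.null(trace$occ_history)) {
    trace$occ_history[[as.character(trace$cycle)]] <- trace$occ
  }
  trace
}

# trim the preallocated per-cycle ledger and expose it as a data.frame
finalize_trace <- function(trace) {
  trace$cycles <- as.data.frame(
    trace$cycles[seq_len(trace$n_rows), , drop = FALSE])
  trace
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace: cycle ", x$cycle, ", alive ",
      format(sum(x$occ), digits = 6), ", dead ",
      format(x$dead, digits = 6), ">\n", sep = "")
  invisible(x)
}

#' Build the initial cohort
#'
#' Allocates the cohort (default 10,000 smokers) across strata by cohort
#' share and, within each stratum, across the mutually exclusive disease
#' states by prevalence; the remainder starts disease-free. Everyone starts
#' as a smoker; no one is dead.
#'
#' @param ps a validated [cea_params()] object.
#' @param keep_history keep per-cycle occupancy arrays (memory-heavier;
#'   disable for large PSA runs).
#' @return a `cohort_trace` at cycle 0.
#' @export
build_initial_cohort <- function(ps, keep_history = TRUE) {
  st <- ps$strata
  n_s <- nrow(st)
  n_d <- length(ps$diseases)
  occ <- array(0, c(N_BINS, 1L + n_d, n_s),
               dimnames = list(NULL, c("none", names(ps$diseases)),
                               st$stratum_id))
  totals <- ps$economics$cohort_size * st$cohort_share
  prev <- vapply(ps$diseases,
                 function(d) unname(d$prevalence[st$stratum_id]),
                 numeric(n_s))
  prev <- matrix(prev, n_s, n_d)
  for (s in seq_len(n_s)) {
    occ[1L, 1L, s] <- totals[s] * (1 - sum(prev[s, ]))
    occ[1L, 1L + seq_len(n_d), s] <- totals[s] * prev[s, ]
  }
  trace <- new_trace(occ, dead = 0, cycle = 0L, age = st$mean_age, ps,
                     keep_history = keep_history)
  trace <- record_cycle(trace, 0, 0, 0, 0)
  trace
}

#' Accrue one cycle's costs and QALYs
#'
#' Sums annual disease costs and utility-weighted life years over the
#' current occupancy (baseline utility for disease-free members, the
#' disease utility weight otherwise) and discounts at
#' `(1 + discount_rate)^(-cycle)`.
#'
#' @param trace a `cohort_trace`.
#' @param ps a [cea_params()] object.
#' @param rates optional precomputed rate arrays (internal memoization).
#' @return list with `cost`, `qaly`, `cost_disc`, `qaly_disc`.
#' @export
accrue <- function(trace, ps, rates = NULL) {
  if (is.null(rates)) rates <- get_rates(ps, trace$age)
  occ <- trace$occ
  n_d <- length(rates$cost)
  occ_d <- occ[, 1L + seq_len(n_d), , drop = FALSE]
  cost <- sum(occ_d * rates$cost_arr)
  qaly <- sum(occ[, 1L, ] * rates$bu_mat) + sum(occ_d * rates$util_arr)
  disc <- (1 + ps$economics$discount_rate)^(-trace$cycle)
  list(cost = cost, qaly = qaly,
       cost_disc = cost * disc, qaly_disc = qaly * disc)
}

#' Apply the quit attempt (cycle 1)
#'
#' From the cycle-0 trace: a fraction `p_abstain` of every smoker state
#' becomes a quitter with years-since-quit counter 1; the fatal fraction of
#' self-harm events moves members to dead; depression and nonfatal
#' self-harm generate one-off costs and QALY decrements for the whole
#' treated cohort; the course cost is charged once per treated member. All
#' cycle-1 amounts (annual accrual plus the one-offs) are discounted at
#' cycle 1.
#'
#' @param trace a `cohort_trace` at cycle 0.
#' @param profile one row of an `intervention_profiles` table (list-like
#'   with `p_abstain`, `p_depression`, `p_selfharm`, `course_cost`).
#' @param ps a [cea_params()] object.
#' @return a `cohort_trace` at cycle 1.
#' @export
apply_quit_attempt <- function(trace, profile, ps) {
  stopifnot(inherits(trace, "cohort_trace"), trace$cycle == 0L)
  ae <- ps$adverse_events
  occ <- trace$occ
  n0 <- sum(occ)

  frac_fatal <- ae$fatal_fraction_selfharm * profile$p_selfharm
  trace$dead <- trace$dead + n0 * frac_fatal
  occ <- occ * (1 - frac_fatal)

  quitters <- occ[1L, , , drop = FALSE] * profile$p_abstain
  occ[2L, , ] <- occ[2L, , , drop = FALSE] + quitters
  occ[1L, , ] <- occ[1L, , , drop = FALSE] * (1 - profile$p_abstain)

  trace$occ <- occ
  trace$cycle <- 1L
  acc <- accrue(trace, ps)

  one_off_cost <- n0 * (profile$course_cost +
                          profile$p_depression * ae$cost_depression +
                          profile$p_selfharm *
                            (1 - ae$fatal_fraction_selfharm) * ae$cost_selfharm)
  one_off_dis <- n0 * (profile$p_depression * ae$disutility_depression +
                         profile$p_selfharm *
                           (1 - ae$fatal_fraction_selfharm) *
                           ae$disutility_selfharm)
  disc <- (1 + ps$economics$discount_rate)^(-1)

  record_cycle(trace,
               cost = acc$cost + one_off_cost,
               qaly = acc$qaly - one_off_dis,
               cost_disc = acc$cost_disc + one_off_cost * disc,
               qaly_disc = acc$qaly_disc - one_off_dis * disc)
}

#' Advance the cohort by one cycle
#'
#' Applies, in order: (1) relapse — quitters revert to smoker with the
#' annual probability of their years-since-quit class and never re-quit;
#' (2) disease incidence — disease-free members acquire each disease with
#' the never-smoker incidence of their current age band scaled by the risk
#' ratio of their smoking status (clamped at 1, counted); (3) mortality —
#' all-cause plus, for diseased members, excess mortality scaled by the same
#' status risk ratios; (4) counters and ages advance, band-boundary
#' crossers adopt the next band's rates, and members beyond the maximum age
#' are removed. The new cycle's costs and QALYs are then accrued.
#'
#' @param trace a `cohort_trace` at cycle >= 1.
#' @param ps a [cea_params()] object.
#' @param rate_cache optional environment used to memoize the per-band rate
#'   arrays across cycles.
#' @return the `cohort_trace` at the next cycle.
#' @export
transition <- function(trace, ps, rate_cache = NULL) {
  stopifnot(inherits(trace, "cohort_trace"), trace$cycle >= 1L)
  rates <- get_rates(ps, trace$age, rate_cache)
  occ <- trace$occ
  n_d <- length(rates$cost)

  # (1) relapse
  rel <- c(0, ps$relapse$p_relapse_short, ps$relapse$p_relapse_long,
           ps$relapse$p_relapse_10plus)[
    match(bin_relapse_class(), c("none", "short", "long", "10plus"))]
  moved <- occ * rel
  occ <- occ - moved
  occ[1L, , ] <- occ[1L, , ] + colSums(moved, dims = 1)

  # (2) incidence (disease-free only)
  healthy <- occ[, 1L, ]                                # 12 x n_s
  for (d in seq_len(n_d)) {
    occ[, 1L + d, ] <- occ[, 1L + d, ] + healthy * rates$p_inc[, d, ]
  }
  occ[, 1L, ] <- healthy * (1 - rates$p_inc_tot)

  # (3) mortality
  deaths <- occ * rates$p_die
  occ <- occ - deaths
  trace$dead <- trace$dead + sum(deaths)
  trace$n_clamped <- trace$n_clamped + rates$n_clamped

  # (4) counters and ages advance
  top <- occ[11L, , ] + occ[12L, , ]
  occ[3:11, , ] <- occ[2:10, , , drop = FALSE]
  occ[12L, , ] <- top
  occ[2L, , ] <- 0
  trace$age <- trace$age + 1L
  beyond <- trace$age > ps$economics$horizon
  if (any(beyond)) {
    trace$dead <- trace$dead + sum(occ[, , beyond])
    occ[, , beyond] <- 0
  }

  trace$occ <- occ
  trace$cycle <- trace$cycle + 1L

  # accrual uses the post-advance age bands (baseline utility can change at
  # a band boundary)
  acc <- accrue(trace, ps, rates = get_rates(ps, trace$age, rate_cache))
  record_cycle(trace, acc$cost, acc$qaly, acc$cost_disc, acc$qaly_disc)
}

#' Run the cohort to the end of life
#'
#' Applies the quit attempt at cycle 1 and then transitions annually until
#' every member is dead or past the maximum age. Per-member totals are
#' cohort totals divided by the cohort size.
#'
#' @param profile one intervention's profile (row of
#'   [build_profiles()] output).
#' @param ps a validated [cea_params()] object.
#' @param keep_history keep per-cycle occupancy arrays in the trace.
#' @return list with `cost_pp` and `qaly_pp` (total discounted GBP and
#'   QALYs per cohort member) and the full `trace`.
#' @export
run_cohort <- function(profile, ps, keep_history = FALSE) {
  trace <- build_initial_cohort(ps, keep_history = keep_history)
  trace <- apply_quit_attempt(trace, profile, ps)
  cache <- new.env(parent = emptyenv())
  max_cycles <- ps$economics$horizon + 1L
  while (sum(trace$occ) > 1e-9 && trace$cycle < max_cycles) {
    trace <- transition(trace, ps, rate_cache = cache)
  }
  trace <- finalize_trace(trace)
  n <- ps$economics$cohort_size
  list(cost_pp = sum(trace$cycles$cost_disc) / n,
       qaly_pp = sum(trace$cycles$qaly_disc) / n,
       trace = trace)
}

#' Export a cohort trace as a tidy table
#'
#' @param trace a `cohort_trace` run with `keep_history = TRUE`.
#' @return data.frame with columns `cycle`, `stratum`, `smoking_bin`,
#'   `disease`, `occupancy`.
#' @export
trace_occupancy <- function(trace) {
  if (is.null(trace$occ_history)) {
    stop("trace was run without keep_history = TRUE")
  }
  dis <- c("none", trace$dims$diseases)
  out <- lapply(names(trace$occ_history), function(cy) {
    occ <- trace$occ_history[[cy]]
    df <- expand.grid(smoking_bin = seq_len(N_BINS), disease = dis,
                      stratum = trace$dims$strata, stringsAsFactors = FALSE)
    df$cycle <- as.integer(cy)
    df$occupancy <- as.vector(occ)
    df
  })
  out <- do.call(rbind, out)
  out[out$occupancy > 0, c("cycle", "stratum", "smoking_bin", "disease",
                           "occupancy")]
}
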