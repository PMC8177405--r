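# Cohort engine invariants and hand-computed oracles.

test_that("the initial cohort allocates shares and prevalences exactly", {
  ps <- toy_params(prevalence = 0.1, cohort_size = 1000, shares = c(0.5, 0.5))
  trace <- build_initial_cohort(ps)
  expect_equal(sum(trace$occ), 1000)
  expect_equal(trace$dead, 0)
  # everyone starts as a smoker (bin 1)
  expect_equal(sum(trace$occ[1L, , ]), 1000)
  expect_equal(sum(trace$occ[-1L, , ]), 0)
  # per-stratum totals and disease split
  expect_equal(unname(apply(trace$occ, 3, sum)), c(500, 500))
  expect_equal(sum(trace$occ[, "COPD", ]), 100)
  expect_equal(sum(trace$occ[, "none", ]), 900)

  ps2 <- generate_default_parameters()
  tr2 <- build_initial_cohort(ps2)
  expect_equal(sum(tr2$occ), 10000)
  expect_equal(unname(apply(tr2$occ, 3, sum)),
               10000 * ps2$strata$cohort_share)
})

test_that("the quit attempt splits smokers, kills fatal self-harm and charges one-offs", {
  ps <- toy_params(
    adverse_events = list(disutility_depression = 0.2, cost_depression = 900,
                          disutility_selfharm = 0.15, cost_selfharm = 2500,
                          fatal_fraction_selfharm = 0.2))
  trace <- build_initial_cohort(ps)
  profile <- toy_profile(p_abstain = 0.3, p_depression = 0.05,
                         p_selfharm = 0.1, course_cost = 100)
  trace <- apply_quit_attempt(trace, profile, ps)

  # fatal self-harm: 1000 * 0.2 * 0.1 = 20 deaths
  expect_equal(trace$dead, 20)
  expect_equal(sum(trace$occ), 980)
  # survivors split 30% quitters (counter 1 = bin 2), 70% smokers
  expect_equal(sum(trace$occ[2L, , ]), 980 * 0.3)
  expect_equal(sum(trace$occ[1L, , ]), 980 * 0.7)

  # one-off cost: course 100 + depression 0.05*900 + nonfatal self-harm
  # 0.1*0.8*2500, charged to all 1000 members (discount 0 in this toy)
  cost1 <- trace$cycles[2, "cost"]
  expect_equal(unname(cost1), 1000 * (100 + 0.05 * 900 + 0.1 * 0.8 * 2500))
  # cycle-1 QALYs: 980 alive at utility 1 minus the one-off decrements
  qaly1 <- trace$cycles[2, "qaly"]
  expect_equal(unname(qaly1),
               980 - 1000 * (0.05 * 0.2 + 0.1 * 0.8 * 0.15))

  # a quit attempt can only be applied to a cycle-0 trace
  expect_error(apply_quit_attempt(trace, profile, ps))
})

test_that("cycle-1 one-offs are discounted one period", {
  ps <- toy_params(discount = 0.05)
  trace <- build_initial_cohort(ps)
  profile <- toy_profile(p_abstain = 0, course_cost = 105)
  trace <- apply_quit_attempt(trace, profile, ps)
  expect_equal(unname(trace$cycles[2, "cost_disc"]), 1000 * 105 / 1.05)
  expect_equal(unname(trace$cycles[2, "cost"]), 1000 * 105)
})

test_that("relapse moves the expected fraction back to smoking, by counter class", {
  ps <- toy_params(relapse = c(0.13, 0.03, 0.0009), horizon = 120)
  trace <- build_initial_cohort(ps)
  trace <- apply_quit_attempt(trace, toy_profile(p_abstain = 1), ps)
  expect_equal(sum(trace$occ[2L, , ]), 1000)

  trace <- transition(trace, ps)
  # 13% of counter-1 quitters relapse; the rest advance to counter 2 (bin 3)
  expect_equal(sum(trace$occ[1L, , ]), 130)
  expect_equal(sum(trace$occ[3L, , ]), 870)
  expect_equal(sum(trace$occ), 1000)

  # four more short-class cycles, then one long-class cycle (3%) as the
  # survivors cross into counters 5-9 (bins 6-10)
  for (i in 1:4) trace <- transition(trace, ps)
  in_long <- sum(trace$occ[6:10, , ])
  expect_equal(in_long, 1000 * (1 - 0.13)^4 * (1 - 0.03))
  trace2 <- transition(trace, ps)
  # the long-run class now relapses at 3%
  relapsed_now <- sum(trace2$occ[1L, , ]) - sum(trace$occ[1L, , ])
  expect_equal(relapsed_now, in_long * 0.03)
})

test_that("relapsed members never re-quit", {
  ps <- toy_params(relapse = c(0.5, 0.5, 0.5), horizon = 120)
  trace <- build_initial_cohort(ps)
  trace <- apply_quit_attempt(trace, toy_profile(p_abstain = 1), ps)
  for (i in 1:10) trace <- transition(trace, ps)
  smokers_before <- sum(trace$occ[1L, , ])
  trace <- transition(trace, ps)
  # the smoker pool can only grow: no flow out of bin 1
  expect_gte(sum(trace$occ[1L, , ]), smokers_before)
})

test_that("mass is conserved and death is absorbing over randomized 50-cycle sweeps", {
  set.seed(2024)
  for (rep in 1:5) {
    ps <- toy_params(
      acm = stats::runif(1, 0, 0.05),
      incidence = stats::runif(1, 0, 0.05),
      prevalence = stats::runif(1, 0, 0.3),
      excess = stats::runif(1, 0, 0.3),
      rr = sort(stats::runif(3, 0.5, 5), decreasing = TRUE),
      relapse = sort(stats::runif(3, 0, 0.3), decreasing = TRUE),
      discount = stats::runif(1, 0, 0.06),
      baseline_utility = stats::runif(1, 0.5, 1),
      disease_utility = stats::runif(1, 0.3, 1),
      disease_cost = stats::runif(1, 0, 5000),
      horizon = 120, mean_age = 40)
    expect_identical(nrow(validate_parameters(ps)), 0L)
    trace <- build_initial_cohort(ps)
    trace <- apply_quit_attempt(
      trace, toy_profile(p_abstain = stats::runif(1)), ps)
    dead_prev <- trace$dead
    for (cy in 1:50) {
      trace <- transition(trace, ps)
      expect_true(all(trace$occ >= 0))
      # dead is absorbing: the cumulative count never decreases
      expect_gte(trace$dead, dead_prev - 1e-12)
      dead_prev <- trace$dead
      # conservation: alive + dead = initial cohort, every cycle
      expect_equal(sum(trace$occ) + trace$dead, 1000, tolerance = 1e-9)
    }
  }
})

test_that("with no mortality, no discounting and full utility, QALYs equal person-years", {
  # accrual runs from entry age 40 to the maximum age 49: ten person-years
  ps <- toy_params(acm = 0, incidence = 0, excess = 0, discount = 0,
                   baseline_utility = 1, disease_utility = 1,
                   relapse = c(0.13, 0.03, 0.0009),
                   mean_age = 40, horizon = 49)
  r <- run_cohort(toy_profile(p_abstain = 0.4), ps)
  expect_equal(r$qaly_pp, 10, tolerance = 1e-10)
  expect_equal(r$cost_pp, 0)
})

test_that("discounting follows the closed-form annuity", {
  ps <- toy_params(acm = 0, incidence = 0, discount = 0.035,
                   mean_age = 40, horizon = 49)
  r <- run_cohort(toy_profile(p_abstain = 0), ps)
  expect_equal(r$qaly_pp, sum(1.035^-(1:10)), tolerance = 1e-10)
})

test_that("a three-state toy matches its hand-built matrix-product oracle", {
  ps <- toy_params(acm = 0.02, incidence = 0.02, prevalence = 0.2,
                   excess = 0.1, rr = c(3, 2, 1), discount = 0.03,
                   baseline_utility = 0.9, disease_utility = 0.7,
                   disease_cost = 500, n_strata = 1, shares = 1,
                   mean_age = 40, horizon = 42)
  r <- run_cohort(toy_profile(p_abstain = 0), ps)

  # hand computation: states (healthy smoker, diseased smoker); per cycle,
  # incidence 0.02 * rr_smoker, then mortality (healthy: acm; diseased:
  # acm + excess * rr_smoker); accrual after the transition
  h <- 800; d <- 200
  p_inc <- 0.02 * 3
  p_die_h <- 0.02
  p_die_d <- 0.02 + 0.1 * 3
  cost <- qaly <- 0
  for (cy in 1:3) {
    if (cy > 1) {
      new_d <- h * p_inc
      h <- (h - new_d) * (1 - p_die_h)
      d <- (d + new_d) * (1 - p_die_d)
    }
    disc <- 1.03^-cy
    cost <- cost + disc * 500 * d
    qaly <- qaly + disc * (0.9 * h + 0.7 * d)
  }
  expect_equal(r$cost_pp, cost / 1000, tolerance = 1e-10)
  expect_equal(r$qaly_pp, qaly / 1000, tolerance = 1e-10)
})

test_that("the full default cohort conserves mass to the end of life", {
  ps <- generate_default_parameters()
  prof <- build_profiles(ps$relative_effects, ps$baseline_risks,
                         ps$interventions, harm_map = ps$harm_map)
  r <- run_cohort(prof[prof$intervention_id == "nrt_std", ], ps)
  cyc <- r$trace$cycles
  expect_true(all(abs(cyc$alive + cyc$dead_cum - 10000) < 1e-8))
  # the run terminates: everyone dead or beyond the maximum age
  expect_lt(cyc$alive[nrow(cyc)], 1e-9)
  expect_true(all(diff(cyc$dead_cum) >= -1e-12))
})

test_that("lifetime QALYs increase with abstinence and decrease with risk ratios", {
  ps <- generate_default_parameters()
  q_of_abstain <- vapply(c(0.1, 0.212, 0.4), function(p) {
    run_cohort(toy_profile(p_abstain = p), ps)$qaly_pp
  }, numeric(1))
  expect_true(all(diff(q_of_abstain) > 0))

  # raising every smoker risk ratio lowers lifetime QALYs
  ps_hi <- ps
  for (dd in names(ps_hi$diseases)) {
    ps_hi$diseases[[dd]]$rr_smoker <- ps_hi$diseases[[dd]]$rr_smoker * 1.5
  }
  q_lo <- run_cohort(toy_profile(p_abstain = 0.2), ps)$qaly_pp
  q_hi <- run_cohort(toy_profile(p_abstain = 0.2), ps_hi)$qaly_pp
  expect_lt(q_hi, q_lo)
})

test_that("the occupancy export reflects the recorded history", {
  ps <- toy_params(horizon = 45)
  r <- run_cohort(toy_profile(p_abstain = 0.5), ps, keep_history = TRUE)
  occ <- trace_occupancy(r$trace)
  expect_true(all(occ$occupancy > 0))
  expect_true(all(occ$cycle >= 0))
  # cycle-1 occupancy sums to the surviving cohort
  expect_equal(sum(occ$occupancy[occ$cycle == 1]), 1000)
  r2 <- run_cohort(toy_profile(p_abstain = 0.5), ps, keep_history = FALSE)
  expect_error(trace_occupancy(r2$trace), "keep_history")
})
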