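test_that("expected outcomes are the column means of the draw matrices", {
  m <- toy_nb(cost = cbind(c(10, 20), c(5, 15)),
              qaly = cbind(c(1, 3), c(2, 2)))
  eo <- expected_outcomes(m)
  expect_equal(eo$cost, c(15, 10))
  expect_equal(eo$qaly, c(2, 2))
  expect_equal(eo$intervention_id, c("tx1", "tx2"))
})

test_that("the frontier reproduces textbook dominance on a hand example", {
  pts <- data.frame(
    intervention_id = c("a", "b", "c", "d", "e"),
    cost = c(0, 100, 60, 300, 120),
    qaly = c(0, 1, 0.2, 2.5, 0.9),
    stringsAsFactors = FALSE
  )
  fr <- efficiency_frontier(pts)
  st <- stats::setNames(fr$status, fr$intervention_id)
  # e costs more than b for fewer QALYs: simply dominated
  expect_identical(unname(st["e"]), "dominated")
  # c lies above the a-b segment: extendedly dominated
  # (mixture of a and b at 0.2 QALYs costs 20 < 60)
  expect_identical(unname(st["c"]), "extendedly_dominated")
  expect_identical(unname(st[c("a", "b", "d")]),
                   rep("frontier", 3))
  # sequential ICERs: b vs a = 100/1; d vs b = 200/1.5
  expect_equal(fr$icer[fr$intervention_id == "b"], 100)
  expect_equal(fr$icer[fr$intervention_id == "d"], 200 / 1.5)
  expect_true(is.na(fr$icer[fr$intervention_id == "a"]))
})

test_that("the frontier agrees with the brute-force mixture oracle on random instances", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(3:14, 1)
    pts <- data.frame(
      intervention_id = paste0("tx", seq_len(n)),
      cost = stats::runif(n, 0, 1000),
      qaly = stats::runif(n, 0, 5),
      stringsAsFactors = FALSE
    )
    fr <- efficiency_frontier(pts)
    got <- stats::setNames(fr$status, fr$intervention_id)
    want <- oracle_frontier_status(pts)
    expect_identical(got[names(want)], want)
    # frontier ICERs are strictly increasing
    icers <- fr$icer[fr$status == "frontier"]
    icers <- icers[!is.na(icers)]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
  }
})

test_that("degenerate frontiers are handled", {
  one <- efficiency_frontier(data.frame(intervention_id = "only",
                                        cost = 5, qaly = 1))
  expect_identical(one$status, "frontier")
  expect_true(is.na(one$icer))

  # an exact tie collapses onto one member
  tie <- efficiency_frontier(data.frame(
    intervention_id = c("p", "q"), cost = c(1, 1), qaly = c(1, 1)))
  expect_setequal(tie$status, c("frontier", "dominated"))
})

test_that("incremental net benefit matches the hand oracle and centers the reference", {
  cost <- cbind(c(100, 100, 100, 100), c(150, 150, 150, 150))
  qaly <- cbind(c(1, 1, 1, 1), c(1.1, 1.2, 0.9, 1.0))
  m <- toy_nb(cost, qaly, ids = c("ref", "alt"))
  # per-draw incremental NB at 1000: 1000*dq - dc = c(50, 150, -150, -50)
  res <- net_benefit(m, wtp = 1000, reference = "ref", boot_R = 0)
  expect_equal(res$enb[res$intervention_id == "alt"], 0)
  expect_equal(res$enb[res$intervention_id == "ref"], 0)
  res2 <- net_benefit(m, wtp = 2000, reference = "ref", boot_R = 0)
  # at 2000: c(150, 350, -250, -50), mean 50
  expect_equal(res2$enb[res2$intervention_id == "alt"], 50)
  expect_identical(unlist(res2[res2$intervention_id == "ref",
                               c("enb", "lo", "hi")], use.names = FALSE),
                   c(0, 0, 0))

  # bootstrap interval brackets the mean and is seeded by the caller
  set.seed(1)
  b1 <- net_benefit(m, wtp = 2000, reference = "ref", boot_R = 500)
  set.seed(1)
  b2 <- net_benefit(m, wtp = 2000, reference = "ref", boot_R = 500)
  expect_identical(b1, b2)
  alt <- b1[b1$intervention_id == "alt", ]
  expect_lte(alt$lo, alt$enb)
  expect_gte(alt$hi, alt$enb)

  expect_error(net_benefit(m, 1000, reference = "nope"), "unknown reference")
})

test_that("acceptability curves are normalized step functions with tie-splitting", {
  cost <- cbind(rep(0, 3), rep(10, 3))
  qaly <- cbind(rep(0, 3), rep(1, 3))
  m <- toy_nb(cost, qaly, ids = c("cheap", "effective"))
  cc <- ceac(m, wtp_grid = c(0, 5, 10, 15, 20))
  expect_equal(cc$cheap, c(1, 1, 0.5, 0, 0))
  expect_equal(cc$effective, c(0, 0, 0.5, 1, 1))
  expect_equal(unname(rowSums(cc[, -1])), rep(1, 5))
})

test_that("acceptability curves sum to one under random draws", {
  set.seed(12)
  m <- toy_nb(matrix(stats::runif(300, 0, 5000), 100, 3),
              matrix(stats::runif(300, 0, 3), 100, 3))
  cc <- ceac(m, wtp_grid = seq(0, 50000, by = 5000))
  expect_true(all(abs(rowSums(cc[, -1]) - 1) < 1e-12))
  expect_true(all(cc[, -1] >= 0 & cc[, -1] <= 1))
})

test_that("the rankogram matches exhaustive enumeration, including ties", {
  # three draws, three options, net benefit = -cost (qaly 0, any wtp)
  nbs <- rbind(c(3, 2, 1),   # a first, b second, c third
               c(1, 3, 2),   # b first, c second, a third
               c(2, 2, 5))   # c first, a and b tie over ranks 2-3
  m <- toy_nb(cost = -nbs, qaly = matrix(0, 3, 3), ids = c("a", "b", "c"))
  rk <- rankogram(m, wtp = 20000)
  want <- rbind(
    a = c(1 / 3, 1 / 6, 1 / 2),
    b = c(1 / 3, 1 / 2, 1 / 6),
    c = c(1 / 3, 1 / 3, 1 / 3)
  )
  expect_equal(unname(rk$prob), unname(want), tolerance = 1e-12)
  # doubly stochastic: rows and columns both sum to one
  expect_equal(unname(rowSums(rk$prob)), rep(1, 3))
  expect_equal(unname(colSums(rk$prob)), rep(1, 3))
})

test_that("rank matrices are doubly stochastic under random draws", {
  set.seed(99)
  m <- toy_nb(matrix(stats::rnorm(500, 5000, 500), 100, 5),
              matrix(stats::rnorm(500, 10, 1), 100, 5))
  rk <- rankogram(m, wtp = 20000)
  expect_equal(unname(rowSums(rk$prob)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(colSums(rk$prob)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(rk$prob >= 0))
  expect_true(all(rk$median_rank >= 1 & rk$median_rank <= 5))
  expect_true(all(rk$rank_iqr["q25", ] <= rk$rank_iqr["q75", ]))
})

test_that("a deterministically ordered rankogram is a permutation matrix", {
  nbs <- matrix(rep(c(4, 3, 2, 1), each = 10), 10, 4)
  m <- toy_nb(cost = -nbs, qaly = matrix(0, 10, 4))
  rk <- rankogram(m, wtp = 1)
  expect_equal(unname(rk$prob), diag(4))
  expect_equal(unname(rk$median_rank), 1:4)
})
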