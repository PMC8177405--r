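test_that("EVPI matches two-point enumeration and is zero without uncertainty", {
  # two equiprobable states: perfect information gains 0.5
  nbs <- rbind(c(1, 0), c(0, 1))
  m <- toy_nb(cost = -nbs, qaly = matrix(0, 2, 2))
  expect_equal(evpi(m, wtp = 20000), 0.5)

  # identical draws: nothing to learn
  m0 <- toy_nb(cost = matrix(c(5, 5, 7, 7), 2, 2),
               qaly = matrix(c(1, 1, 2, 2), 2, 2))
  expect_equal(evpi(m0, wtp = 1000), 0)

  # EVPI is never negative
  set.seed(4)
  mr <- toy_nb(matrix(stats::rnorm(200, 1000, 100), 50, 4),
               matrix(stats::rnorm(200, 10, 1), 50, 4))
  expect_gte(evpi(mr, 20000), 0)

  expect_error(evpi(toy_nb(matrix(1, 1, 2), matrix(1, 1, 2)), 100),
               "at least 2 draws")
})

test_that("EVPI agrees with the bivariate-normal closed form", {
  # NB_1 ~ N(0, 1), NB_2 ~ N(0.2, 1.5), independent:
  # E[max] = mu1*pnorm(d) + mu2*pnorm(-d) + theta*dnorm(d),
  # theta = sqrt(s1^2 + s2^2), d = (mu1 - mu2)/theta
  mu <- c(0, 0.2); s <- c(1, 1.5)
  theta <- sqrt(sum(s^2))
  d <- (mu[1] - mu[2]) / theta
  evpi_true <- mu[1] * stats::pnorm(d) + mu[2] * stats::pnorm(-d) +
    theta * stats::dnorm(d) - max(mu)

  set.seed(2718)
  n <- 1e5
  nbs <- cbind(stats::rnorm(n, mu[1], s[1]), stats::rnorm(n, mu[2], s[2]))
  m <- toy_nb(cost = -nbs, qaly = matrix(0, n, 2))
  expect_equal(evpi(m, wtp = 20000), evpi_true, tolerance = 0.03)
})

test_that("population scaling is exact arithmetic in GBP million", {
  expect_equal(population_voi(709, 274021, 1), 709 * 274021 / 1e6)
  expect_equal(population_voi(100, 1e6, 5), 500)
  expect_equal(population_voi(0, 274021, 5), 0)
  expect_error(population_voi(-1))
})

test_that("EVPPI vanishes for pure-noise parameters and reaches EVPI for decisive ones", {
  set.seed(31)
  n <- 2000
  x <- stats::rnorm(n)
  noise <- matrix(stats::rnorm(2 * n, 0, 5), n, 2)
  nbs <- cbind(100 * x, -100 * x) + noise
  m <- toy_nb(cost = -nbs, qaly = matrix(0, n, 2))
  ev <- evpi(m, 20000)

  z <- stats::rnorm(n)  # unrelated to the net benefit
  ev_noise <- evppi(m, cbind(z = z), 20000)
  expect_lt(ev_noise, 0.08 * ev)

  ev_x <- evppi(m, cbind(x = x), 20000)
  # x drives nearly all the decision uncertainty
  expect_gt(ev_x, 0.9 * ev)
  expect_lt(ev_x, 1.1 * ev)

  # constant column: zero with a message
  expect_message(ev0 <- evppi(m, cbind(const = rep(1, n)), 20000),
                 "constant")
  expect_equal(ev0, 0)
})

test_that("regression EVPPI agrees with the nested Monte-Carlo oracle on a 1-parameter toy", {
  # NB_1 = 100 x + e1, NB_2 = -100 x + e2: EVPPI(x) = 100 E|x| = 100 sqrt(2/pi)
  set.seed(57)
  n <- 3000
  x <- stats::rnorm(n)
  nbs <- cbind(100 * x, -100 * x) + matrix(stats::rnorm(2 * n, 0, 50), n, 2)
  m <- toy_nb(cost = -nbs, qaly = matrix(0, n, 2))
  ev_reg <- evppi(m, cbind(x = x), 20000)

  # oracle: inner expectation over the noise taken analytically (the
  # conditional means are known), outer expectation over the same x draws,
  # so the comparison isolates the regression error
  ev_oracle <- mean(pmax(100 * x, -100 * x)) -
    max(mean(100 * x), mean(-100 * x))
  expect_equal(ev_reg, ev_oracle, tolerance = 0.05)

  analytic <- 100 * sqrt(2 / pi)
  expect_equal(ev_oracle, analytic, tolerance = 0.1)
})

test_that("regression EVPPI agrees with the oracle on a 2-parameter toy", {
  # NB_i = 50 x_i + noise: EVPPI(x1, x2) = 50 E[max(x1, x2)] = 50/sqrt(pi)
  set.seed(58)
  n <- 3000
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  nbs <- cbind(50 * x1, 50 * x2) + matrix(stats::rnorm(2 * n, 0, 20), n, 2)
  m <- toy_nb(cost = -nbs, qaly = matrix(0, n, 2))
  ev_reg <- evppi(m, cbind(x1 = x1, x2 = x2), 20000)
  ev_oracle <- mean(pmax(50 * x1, 50 * x2)) -
    max(mean(50 * x1), mean(50 * x2))
  expect_equal(ev_reg, ev_oracle, tolerance = 0.05)
  expect_equal(ev_oracle, 50 / sqrt(pi), tolerance = 0.1)

  # knowing only x1 is worth less than knowing both
  ev_x1 <- evppi(m, cbind(x1 = x1), 20000)
  expect_lt(ev_x1, ev_reg)
})

test_that("large subsets fall back to the principal-component projection", {
  set.seed(59)
  n <- 800
  # one latent factor loading on all eight parameters, so the leading
  # principal component carries the decision-relevant signal
  f <- stats::rnorm(n)
  X <- matrix(stats::rnorm(n * 8, 0, 0.3), n, 8,
              dimnames = list(NULL, paste0("p", 1:8))) + f
  nbs <- cbind(40 * f, -40 * f) +
    matrix(stats::rnorm(2 * n, 0, 10), n, 2)
  m <- toy_nb(cost = -nbs, qaly = matrix(0, n, 2))
  ev8 <- evppi(m, X, 20000, max_smooth_dims = 4L)
  ev <- evpi(m, 20000)
  expect_gte(ev8, 0)
  # the latent factor dominates the leading component, so the projection
  # keeps most of the decision-relevant signal
  expect_gt(ev8, 0.5 * ev)

  expect_error(evppi(m, X[1:10, ], 20000), "row-aligned")
  expect_error(evppi(m, X[, 0], 20000), "empty parameter subset")
})

test_that("the VoI report caps EVPPI at EVPI and scales to population values", {
  set.seed(61)
  n <- 600
  x <- stats::rnorm(n); z <- stats::rnorm(n)
  nbs <- cbind(80 * x, -80 * x) + matrix(stats::rnorm(2 * n, 0, 30), n, 2)
  pm <- cbind(x = x, z = z)
  m <- toy_nb(cost = -nbs, qaly = matrix(0, n, 2), ids = c("t1", "t2"))
  subsets <- list(all = list(cols = colnames(pm)),
                  signal = list(cols = "x"),
                  noise = list(cols = "z"),
                  pair_restricted = list(cols = "x",
                                         interventions = c("t1", "t2")))
  rpt <- voi_report(m, pm, wtp = 20000, population = 274021L,
                    subsets = subsets)
  expect_s3_class(rpt, "voi_report")
  expect_identical(rpt$subset,
                   c("all", "signal", "noise", "pair_restricted"))
  ev <- attr(rpt, "evpi_pp")
  expect_equal(rpt$evppi_pp[rpt$subset == "all"], ev)
  expect_true(all(rpt$evppi_pp >= 0 & rpt$evppi_pp <= ev + 1e-12))
  expect_equal(rpt$pop_1y_million, rpt$evppi_pp * 274021 / 1e6)
  expect_equal(rpt$pop_5y_million, 5 * rpt$pop_1y_million)

  expect_error(
    voi_report(m, pm, 20000, subsets = list(bad = list(cols = "missing"))),
    "unknown parameters")
  expect_error(quitcea:::restrict_nb(m, c("t1", "absent")), "missing")
})
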