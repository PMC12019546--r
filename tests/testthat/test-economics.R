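two_normal_model <- function(rho, sd = 1) {
  corr <- matrix(c(1, rho, rho, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  price_model(tibble::tibble(commodity = c("a", "b"), family = "normal",
                             p1 = 0, p2 = sd, p3 = NA), corr)
}

test_that("copula draws respect marginals and the target correlation", {
  # identity correlation: empirical correlation near zero
  m0 <- two_normal_model(0)
  d0 <- sample_prices(m0, 20000, seed = 1)
  expect_lt(abs(stats::cor(d0$a, d0$b)), 0.02)
  # perfect correlation with identical marginals: identical draws
  m1 <- two_normal_model(1)
  d1 <- sample_prices(m1, 500, seed = 2)
  expect_equal(d1$a, d1$b, tolerance = 1e-9)
  # rho = 0.7 recovered within 0.02 at n = 50,000
  m7 <- two_normal_model(0.7)
  d7 <- sample_prices(m7, 50000, seed = 3)
  expect_lt(abs(stats::cor(d7$a, d7$b) - 0.7), 0.02)
  expect_lt(abs(stats::cor(d7$a, d7$b, method = "spearman") -
                  6 / pi * asin(0.7 / 2)), 0.02)
})

test_that("marginal families are honoured and invalid ones rejected", {
  m <- price_model(tibble::tribble(
    ~commodity, ~family, ~p1, ~p2, ~p3,
    "ln", "lognormal", log(10), 0.2, NA,
    "pt", "pert", 2, 3, 6))
  d <- sample_prices(m, 40000, seed = 4)
  expect_true(all(d$ln > 0))
  expect_lt(abs(mean(log(d$ln)) - log(10)), 0.01)
  expect_true(all(d$pt > 2 & d$pt < 6))
  # PERT mean is (min + 4 mode + max) / 6
  expect_lt(abs(mean(d$pt) - (2 + 4 * 3 + 6) / 6), 0.02)
  expect_error(price_model(tibble::tibble(commodity = "x", family = "gamma",
                                          p1 = 1, p2 = 1, p3 = NA)),
               "gamma")
})

test_that("a non-positive-definite correlation names the matrix", {
  corr <- matrix(c(1, 2, 2, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  m <- price_model(tibble::tibble(commodity = c("a", "b"), family = "normal",
                                  p1 = 0, p2 = 1, p3 = NA), corr)
  expect_error(sample_prices(m, 10, seed = 1),
               class = "grazenet_decomposition_error")
})

test_that("operating profit reproduces a hand-kept ledger to the cent", {
  production <- list(meat_mg = 213.5, wool_mg = 2.0, purchased_feed_mg = 300)
  prices <- tibble::tibble(meat = 3.20, wool = 12.00, feed = 350)
  econ <- list(overheads = 150000, variable_other = 120000,
               capex = 50000, capex_life = 10,
               cost_delta = 8000, income_delta = 96000)
  ledger <- 213.5 * 1000 * 3.20 + 2.0 * 1000 * 12.00 + 96000 -
    300 * 350 - 120000 - 150000 - 8000 - 50000 / 10
  expect_equal(operating_profit(production, prices, econ), ledger,
               tolerance = 1e-9)
  # all zeros give zero
  expect_equal(operating_profit(list(meat_mg = 0, wool_mg = 0,
                                     purchased_feed_mg = 0),
                                tibble::tibble(meat = 0, wool = 0, feed = 0),
                                list(overheads = 0, variable_other = 0,
                                     capex = 0, capex_life = 10,
                                     cost_delta = 0, income_delta = 0)), 0)
})

test_that("the Monte Carlo is seeded, degenerate-safe and shrinks as 1/sqrt(n)", {
  production <- list(meat_mg = 100, wool_mg = 10, purchased_feed_mg = 50)
  econ <- list(overheads = 10000, variable_other = 5000, capex = 0,
               capex_life = 10, cost_delta = 0, income_delta = 0)
  model <- default_price_model("beef")
  a <- monte_carlo_profit(production, model, econ, n = 2000, seed = 11)
  b <- monte_carlo_profit(production, model, econ, n = 2000, seed = 11)
  expect_identical(a$iterations, b$iterations)
  expect_equal(a$n, 2000)
  # degenerate marginals: every iteration identical
  degen <- price_model(tibble::tibble(
    commodity = c("meat", "wool", "feed"), family = "normal",
    p1 = c(3, 12, 350), p2 = 0, p3 = NA))
  d <- monte_carlo_profit(production, degen, econ, n = 50, seed = 1)
  expect_equal(stats::sd(d$iterations), 0)
  # standard error scaling on a linear profit
  small <- monte_carlo_profit(production, model, econ, n = 100, seed = 5)
  big <- monte_carlo_profit(production, model, econ, n = 10000, seed = 5)
  se_ratio <- (big$summary$sd / sqrt(big$n)) / (small$summary$sd / sqrt(small$n))
  expect_gt(se_ratio, 0.1 / 1.5)
  expect_lt(se_ratio, 0.1 * 1.5)
})

test_that("profit at mean prices equals the Monte Carlo mean for linear profit", {
  production <- list(meat_mg = 100, wool_mg = 10, purchased_feed_mg = 50)
  econ <- list(overheads = 0, variable_other = 0, capex = 0, capex_life = 10,
               cost_delta = 0, income_delta = 0)
  model <- price_model(tibble::tibble(
    commodity = c("meat", "wool", "feed"), family = "normal",
    p1 = c(3, 12, 350), p2 = c(0.3, 1.2, 35), p3 = NA))
  mc <- monte_carlo_profit(production, model, econ, n = 50000, seed = 7)
  at_mean <- operating_profit(production,
                              tibble::tibble(meat = 3, wool = 12, feed = 350),
                              econ)
  expect_lt(abs(mc$summary$mean - at_mean) / abs(at_mean), 0.01)
})

test_that("the carbon account taxes or credits exclusively and continuously", {
  pol <- carbon_policy()
  zero <- carbon_account(0, pol, 1000)
  expect_equal(zero$tax, 0); expect_equal(zero$credit_income, 0)
  expect_equal(zero$post_account_profit, 1000)
  expect_equal(carbon_account(10, pol)$tax, 800)
  expect_equal(carbon_account(-5, pol)$credit_income, 140)
  withr::with_seed(42, {
    nets <- runif(500, -1000, 1000)
    for (net in nets) {
      acc <- carbon_account(net, pol, 0)
      expect_true(acc$tax == 0 || acc$credit_income == 0)
      expect_gte(acc$tax, 0); expect_gte(acc$credit_income, 0)
    }
  })
  eps <- 1e-9
  expect_lt(abs(carbon_account(eps, pol, 0)$post_account_profit -
                  carbon_account(-eps, pol, 0)$post_account_profit), 1e-6)
  expect_error(carbon_policy(tax_rate = 20, credit_price = 28),
               class = "grazenet_parameter_error")
  expect_error(carbon_policy(tax_rate = -1),
               class = "grazenet_parameter_error")
})

test_that("MACC points are ordered by cost with side lists for edge cases", {
  results <- tibble::tribble(
    ~scenario, ~profit, ~net,
    "baseline", 1000, 100,
    "winwin",   1100,  80,    # negative cost
    "costly",    900,  96,    # $25 per Mg
    "same",     1000, 100,    # zero abatement
    "worse",     950, 120)    # emission-increasing
  m <- macc(results)
  expect_equal(m$curve$scenario, c("winwin", "costly"))
  expect_equal(m$curve$cost_per_mg[m$curve$scenario == "costly"], 25)
  expect_lt(m$curve$cost_per_mg[1], 0)
  expect_equal(m$excluded$scenario, "same")
  expect_equal(m$emission_increasing$scenario, "worse")
  # exhaustive pairwise ordering oracle on the curve
  cc <- m$curve$cost_per_mg
  for (i in seq_along(cc)) for (j in seq_along(cc)) {
    if (i < j) expect_lte(cc[i], cc[j])
  }
  # scale invariance of the ordering
  scaled <- results; scaled$profit <- scaled$profit * 7
  scaled$net <- scaled$net   # costs scale but order is preserved
  m2 <- macc(scaled)
  expect_equal(m2$curve$scenario, m$curve$scenario)
  expect_error(macc(results, baseline = "nope"), "nope")
})
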