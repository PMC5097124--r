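test_that("distribution fits are the closed-form MLEs", {
  expect_equal(fit_direct_spend(c(1, 2, 3)), 0.5)
  expect_equal(fit_direct_spend(rep(7, 10)), 1 / 7)
  expect_error(fit_direct_spend(c(1, -2)), "> 0")
  expect_error(fit_direct_spend(100), "at least 2")

  m <- fit_multiplier(c(2, 3, 4))
  expect_equal(m$mean, 3)
  expect_equal(m$sd, 1)
  expect_equal(fit_multiplier(rep(2.5, 6))$sd, 0)
  expect_error(fit_multiplier(2), "at least 2")

  # recovery on a large synthetic sample
  set.seed(12)
  big <- rexp(1e5, 1 / 200)
  expect_lt(abs(1 / fit_direct_spend(big) - 200), 3 * 200 / sqrt(1e5))
})

test_that("the truncated-normal mean oracle is analytic", {
  expect_equal(poachval:::truncnorm_mean(3, 0, 1), 3)
  # half-normal at the truncation point: 1 + sd * sqrt(2/pi)
  expect_equal(poachval:::truncnorm_mean(1, 1, 1), 1 + sqrt(2 / pi),
               tolerance = 1e-12)
  expect_equal(round(poachval:::truncnorm_mean(1, 1, 1), 4), 1.7979)
  ora <- expected_loss_oracle(loss_table(100),
                              spend_distributions(1 / 200, 3, 0))
  expect_equal(ora$direct, 20000)
  expect_equal(ora$indirect, 40000)
})

test_that("Monte Carlo means agree with the closed-form oracle", {
  dist <- spend_distributions(1 / 200, 3, 0)
  val <- simulate_valuation(loss_table(100), dist, n_draws = 1e5,
                            seed = 21, keep_draws = TRUE)
  se_d <- sd(val$draws$overall_direct) / sqrt(1e5)
  se_i <- sd(val$draws$overall_indirect) / sqrt(1e5)
  expect_lt(abs(val$overall$direct.mean - 20000), 3 * se_d)
  expect_lt(abs(val$overall$indirect.mean - 40000), 3 * se_i)
  expect_identical(val$n_draws, 100000L)
})

test_that("zero visit losses give exactly zero monetary losses", {
  dist <- spend_distributions(1 / 150, 2.5, 0.6)
  val <- simulate_valuation(loss_table(c(0, 0, 0)), dist, n_draws = 500,
                            seed = 2)
  expect_true(all(val$per_pa[, -(1:3)] == 0))
  expect_true(all(val$overall == 0))
})

test_that("valuation draws are seeded, equivariant and internally coherent", {
  losses <- loss_table(c(40, 70, 10, 200),
                       region = c("east", "south", "west", "east"))
  dist <- spend_distributions(1 / 180, 2.8, 0.8)
  a <- simulate_valuation(losses, dist, n_draws = 3000, seed = 5,
                          keep_draws = TRUE)
  b <- simulate_valuation(losses, dist, n_draws = 3000, seed = 5,
                          keep_draws = TRUE)
  expect_identical(a, b)

  # scale equivariance: doubling every visit loss doubles every draw
  losses2 <- losses; losses2$visit_loss <- losses2$visit_loss * 2
  d2 <- simulate_valuation(losses2, dist, n_draws = 3000, seed = 5,
                           keep_draws = TRUE)
  expect_equal(d2$draws$overall_total, 2 * a$draws$overall_total)

  # total = direct + indirect per draw; quantile ordering
  expect_equal(a$draws$overall_total,
               a$draws$overall_direct + a$draws$overall_indirect)
  for (q in c("direct", "indirect", "total")) {
    expect_true(all(a$by_region[[paste0(q, ".q2.5")]] <=
                      a$by_region[[paste0(q, ".q97.5")]]))
    expect_true(all(a$by_region[[paste0(q, ".q2.5")]] <=
                      a$by_region[[paste0(q, ".mean")]]))
    expect_true(all(a$by_region[[paste0(q, ".mean")]] <=
                      a$by_region[[paste0(q, ".q97.5")]]))
  }
  # regional decomposition sums to the overall mean
  expect_equal(sum(a$by_region$total.mean), a$overall$total.mean)
  expect_error(simulate_valuation(losses[0, ], dist, 100, 1), "no visit")
})

test_that("simulated means track the oracle across configurations", {
  configs <- list(
    list(losses = loss_table(c(10, 20), region = c("east", "west")),
         dist = spend_distributions(1 / 100, 2, 0.5)),
    list(losses = loss_table(500, region = "central"),
         dist = spend_distributions(1 / 350, 1.2, 1.0)),
    list(losses = loss_table(c(5, 5, 5), region = "south"),
         dist = spend_distributions(1 / 80, 4, 0.01)))
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    val <- simulate_valuation(cf$losses, cf$dist, n_draws = 2e4,
                              seed = 30 + k, keep_draws = TRUE)
    ora <- expected_loss_oracle(cf$losses, cf$dist)
    se <- sd(val$draws$overall_total) / sqrt(2e4)
    expect_lt(abs(val$overall$total.mean - ora$total), 3 * se)
  }
})
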