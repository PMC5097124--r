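test_that("range-to-normal conversion matches the 95% CI interpretation", {
  got <- range_to_normal(800, 1200)
  expect_equal(got$mean, 1000)
  expect_equal(got$sd, 400 / (2 * qnorm(0.975)))  # 102.04
  expect_equal(round(got$sd, 2), 102.04)
  # degenerate range collapses to a point
  expect_equal(range_to_normal(500, 500), data.frame(mean = 500, sd = 0))
  # inverse of the quantile formula: a range of 2 * 1.959964 has sd 1
  expect_equal(range_to_normal(0, 2 * qnorm(0.975))$sd, 1)
  expect_error(range_to_normal(10, 5), "lo must be <= hi")
})

test_that("the sd imputation line reproduces the empirical relation", {
  expect_equal(impute_population_sd(10000), 1412)
  expect_equal(impute_population_sd(0), 192)
  expect_equal(impute_population_sd(1000), 314)
  expect_error(impute_population_sd(-5), ">= 0")
  expect_error(imputation_params(slope = -1), ">= 0")
})

test_that("the design applies the declared transforms", {
  tab <- tiny_pa_table()
  des <- build_design(tab)
  i <- which(des$pa_id == "T001")
  expect_equal(unname(des$X[i, "log_area"]), log(100))
  expect_equal(des$y, log(tab$visits))
  # density observation: population mean over censused area
  expect_equal(des$density$mean[i], 2000 / 100)
  expect_equal(des$density$sd[i], 300 / 100)
  # range-form record converted through range_to_normal
  j <- which(des$pa_id == "T002")
  expect_equal(des$density$mean[j], 500 / 200)
  expect_equal(des$density$sd[j], (700 - 300) / (2 * qnorm(0.975)) / 200)
  # no-elephant record fixed at zero; no-uncertainty record flagged
  expect_identical(des$density$form[des$pa_id == "T003"], "zero")
  expect_identical(des$density$form[des$pa_id == "T004"], "none")
})

test_that("non-positive visits and missing covariates are rejected", {
  tab <- tiny_pa_table()
  tab$visits[2] <- 0
  expect_error(build_design(tab), "visits <= 0 at PA 'T002'")
  tab2 <- tiny_pa_table()
  tab2$country_ppp[3] <- NA
  expect_error(build_design(tab2), "country_ppp")
})

test_that("semi-elasticity and marginal-visit arithmetic are exact", {
  expect_equal(round(effect_size_percent(1.55)), 371)
  expect_equal(effect_size_percent(0), 0)
  expect_equal(effect_size_percent(log(2)), 100)
  expect_equal(marginal_visits(1883, 1.55, 0.1), 698.9, tolerance = 1e-4)
  expect_equal(marginal_visits(1883, 1.55, 0), 0)
  expect_equal(marginal_visits(1000, log(2), 1), 1000)
  expect_error(marginal_visits(0, 1, 1), "> 0")
})

test_that("degenerate single-draw fits predict in closed form", {
  # all coefficients zero, intercept log(1000): median 1,000 at any density
  f0 <- degenerate_fit(intercept = log(1000))
  expect_equal(predict_visits(f0, 0)$median, 1000)
  expect_equal(predict_visits(f0, 1.7)$median, 1000)
  # beta_density = 1.55 about a baseline of 1,883: +0.1 density multiplies
  # visits by exp(0.155)
  f1 <- degenerate_fit(intercept = log(1883), b_density = 1.55)
  base <- predict_visits(f1, 0)$median
  up <- predict_visits(f1, 0.1)$median
  expect_equal(up, 1883 * exp(0.155), tolerance = 1e-10)
  expect_equal(up - base, 1883 * (exp(0.155) - 1), tolerance = 1e-10)
  # monotonicity in density for a savannah PA with positive effect
  dens <- seq(0, 2, by = 0.25)
  meds <- vapply(dens, function(d) predict_visits(f1, d)$median, 0)
  expect_true(all(diff(meds) > 0))
  # the interaction cancels the main effect on forested PAs
  f2 <- degenerate_fit(intercept = log(1000), b_density = 1.55,
                       b_interaction = -1.55)
  expect_equal(predict_visits(f2, 1.5, forest = TRUE)$median, 1000)
  expect_error(predict_visits(f1, -0.5), "nonnegative")
})

test_that("perfect and null predictions bracket the R^2 evaluation", {
  # a fit whose predictions are exact: slope 1, intercept 0, R^2 = 1
  tab <- suppressMessages(generate_pa_table(
    synthetic_params(n_pas = 40, n_no_elephant = 10, n_with_visits = 40,
                     residual_sd = 0.02, sd_intercept = 1e-9, sd_slope = 0,
                     sd_jitter = 0, seed = 21)))$pa
  cfg <- quick_config(iters = 400)
  fit <- fit_visitation_model(tab, cfg)
  r2 <- model_fit_r2(fit, tab)
  expect_gt(r2$r_squared, 0.99)
  expect_equal(r2$slope, 1, tolerance = 0.05)
  # predictions unrelated to observations: R^2 near 0
  f0 <- degenerate_fit(intercept = log(1000), n_draws = 50)
  set.seed(4)
  f0$draws[, "intercept"] <- log(1000) + rnorm(50, 0, 0.01)
  r0 <- model_fit_r2(f0, tab)
  expect_lt(r0$r_squared, 0.2)
  expect_error(model_fit_r2(fit, tab[1:2, ]), "at least 3")
})
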