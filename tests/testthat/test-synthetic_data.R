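test_that("the generator is a pure function of its parameters", {
  p <- synthetic_params(seed = 42)
  a <- generate_pa_table(p)
  b <- generate_pa_table(p)
  expect_identical(a, b)
  c <- generate_pa_table(synthetic_params(seed = 43))
  expect_false(identical(a$pa$visits, c$pa$visits))
})

test_that("default design counts match the study structure", {
  g <- generate_pa_table(synthetic_params(seed = 7))
  expect_identical(nrow(g$pa), 270L)           # 216 elephant + 54 without
  expect_identical(sum(!is.na(g$pa$visits)), 164L)
  form <- pa_uncertainty_form(g$pa)
  # oracle: direct filter counts at the declared fractions
  expect_identical(sum(form == "sd"), 93L)     # round(0.43 * 216)
  expect_identical(sum(form == "range"), 26L)  # round(0.12 * 216)
  expect_identical(sum(form == "none"), 97L)   # 216 - 93 - 26 = 216 * 0.45
  expect_identical(sum(form == "zero"), 54L)
  # exactly the designated fraction of PAs exceeds 1,000 reported elephants
  expect_identical(sum(g$pa$elephant_pop_mean > 1000, na.rm = TRUE), 58L)
})

test_that("visits are exactly exp(X beta) when all noise is off", {
  p <- synthetic_params(residual_sd = 0, sd_intercept = 1e-9, sd_slope = 0,
                        sd_jitter = 0, seed = 5)
  g <- generate_pa_table(p)
  expect_equal(g$pa$visits[!is.na(g$pa$visits)],
               exp(g$truth$linear_pred[g$truth$has_visits]))
  # and OLS on the true design recovers the coefficients to tolerance
  keep <- g$truth$has_visits
  d <- g$truth$true_density[keep]
  r <- g$pa[keep, ]
  ols <- lm(log(r$visits) ~ log(r$area_km2) + d + r$forest + I(d * r$forest)
            + r$lion + r$natural_attractiveness + log(r$nearby_population)
            + log(r$accessibility_minutes) + log(r$country_ppp))
  b <- p$true_coefficients
  expect_equal(unname(coef(ols)),
               unname(b[c("intercept", "log_area", "elephant_density",
                          "forest", "density_x_forest", "lion",
                          "natural_attractiveness", "log_nearby_population",
                          "log_accessibility", "log_country_ppp")]),
               tolerance = 1e-8)
})

test_that("uncertainty-form fractions track the parameters", {
  for (fr in list(c(0.6, 0.2), c(0.2, 0.0), c(0.0, 0.5))) {
    g <- generate_pa_table(synthetic_params(frac_sd_form = fr[1],
                                            frac_range_form = fr[2],
                                            seed = 9))
    form <- pa_uncertainty_form(g$pa)
    expect_identical(sum(form == "sd"), as.integer(round(fr[1] * 216)))
    expect_identical(sum(form == "range"), as.integer(round(fr[2] * 216)))
  }
  expect_error(synthetic_params(frac_sd_form = 0.7, frac_range_form = 0.4),
               "<= 1")
})

test_that("reported sds follow the imputation line", {
  g <- generate_pa_table(synthetic_params(seed = 13))
  form <- pa_uncertainty_form(g$pa)
  sd_obs <- g$pa$elephant_pop_sd[form == "sd"]
  mean_obs <- g$pa$elephant_pop_mean[form == "sd"]
  line <- lm(sd_obs ~ mean_obs)
  expect_equal(unname(coef(line)[2]), 0.122, tolerance = 0.15)
  expect_equal(unname(coef(line)[1]), 192, tolerance = 0.15)
})

test_that("spend generator recovers its own parameters at large n", {
  est <- generate_spend_estimates(n_direct = 1e5, n_mult = 1e5,
                                  direct_mean = 200, mult_mean = 2.8,
                                  mult_sd = 0.8, seed = 3)
  # CLT: sample mean within 3 s.e. of the target
  expect_lt(abs(mean(est$direct_spend_usd) - 200), 3 * 200 / sqrt(1e5))
  expect_true(all(est$multipliers >= 1))
  em <- poachval:::truncnorm_mean(2.8, 0.8, 1)
  expect_lt(abs(mean(est$multipliers) - em), 3 * 0.8 / sqrt(1e5))
  # degenerate sd: all multipliers collapse to the mean
  con <- generate_spend_estimates(5, 5, 100, 3, 0, seed = 1)
  expect_equal(con$multipliers, rep(3, 5))
  expect_error(generate_spend_estimates(direct_mean = -1), "> 0")
})

test_that("within-site panels obey the reduced log-linear model", {
  pan <- generate_within_site_panel(n_years = 56, seed = 8)
  expect_identical(nrow(pan), 56L)
  expect_identical(pan, generate_within_site_panel(n_years = 56, seed = 8))
  # zero-noise panel: exact log-linear relation
  b <- c(intercept = 11, log_area = 0.5, log_gdp = -0.4,
         elephant_density = 0.67)
  pan0 <- generate_within_site_panel(n_years = 20, true_coefficients = b,
                                     residual_sd = 0, seed = 2)
  expect_equal(log(pan0$visits),
               as.numeric(b["intercept"] + b["log_area"] * log(pan0$area_km2)
                          + b["log_gdp"] * log(pan0$country_gdp)
                          + b["elephant_density"] * pan0$elephant_density))
  expect_error(generate_within_site_panel(n_years = 5), ">= 10")
})
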