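# MCMC behaviour of the errors-in-variables fit: reproducibility, parameter
# recovery, diagnostics, attenuation, sd imputation, within-site model.

test_that("identical configuration and seed give identical draws", {
  tab <- suppressMessages(generate_pa_table(
    synthetic_params(n_pas = 30, n_no_elephant = 8, n_with_visits = 30,
                     seed = 14)))$pa
  cfg <- quick_config(iters = 200, seed = 99)
  f1 <- fit_visitation_model(tab, cfg)
  f2 <- fit_visitation_model(tab, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_visitation_model(tab, quick_config(iters = 200, seed = 100))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the 95% interval covers the generating density coefficient", {
  g <- generate_pa_table(synthetic_params(residual_sd = 0.3, seed = 31))
  cfg <- quick_config(iters = 800, seed = 2)
  fit <- fit_visitation_model(g$pa, cfg)
  s <- coef_summary(fit)
  bd <- s[s$parameter == "elephant_density", ]
  expect_lt(bd$q2.5, 1.55)
  expect_gt(bd$q97.5, 1.55)
  expect_lt(abs(bd$mean - 1.55), 0.5)

  # total draw count bookkeeping and nonnegative latent densities
  expect_identical(nrow(fit$draws),
                   as.integer(cfg$mcmc$chains * cfg$mcmc$sampling_iters))
  dcols <- grep("^density\\[", colnames(fit$draws))
  expect_true(all(fit$draws[, dcols] >= 0))

  # imputation consistency: posterior means of imputed sds lie on the
  # empirical line (slope within 50% of 0.122)
  des <- build_design(g$pa)
  mis <- des$density$form == "none"
  ids <- des$pa_id[mis]
  post_sd <- colMeans(fit$draws[, paste0("pop_sd[", ids, "]")])
  sl <- coef(lm(post_sd ~ des$density$pop_mean[mis]))[2]
  expect_gt(sl, 0.122 * 0.5)
  expect_lt(sl, 0.122 * 1.5)
})

test_that("a null density effect is recovered as null", {
  p <- synthetic_params(seed = 17, residual_sd = 0.5)
  p$true_coefficients["elephant_density"] <- 0
  p$true_coefficients["density_x_forest"] <- 0
  g <- generate_pa_table(p)
  fit <- fit_visitation_model(g$pa, quick_config(iters = 600, seed = 3))
  s <- coef_summary(fit)
  bd <- s[s$parameter == "elephant_density", ]
  expect_lt(bd$q2.5, 0)
  expect_gt(bd$q97.5, 0)
})

test_that("plugging in noisy point densities attenuates the coefficient", {
  # classical measurement error built by hand: the observed density is the
  # truth plus noise, then the naive OLS slope should sit below the
  # errors-in-variables posterior mean (directionally, over replicates)
  naive <- eiv <- numeric(3)
  for (r in 1:3) {
    g <- generate_pa_table(synthetic_params(
      n_pas = 80, n_no_elephant = 20, n_with_visits = 100,
      residual_sd = 0.3, frac_sd_form = 1, frac_range_form = 0,
      seed = 40 + r))
    tab <- g$pa
    keep <- g$truth$has_visits & g$truth$true_pop > 0
    noise_sd <- 0.6
    tab$elephant_pop_sd[g$truth$true_pop > 0] <-
      noise_sd * tab$censused_area_km2[g$truth$true_pop > 0]
    set.seed(600 + r)
    obs_d <- pmax(0, g$truth$true_density + rnorm(nrow(tab), 0, noise_sd))
    tab$elephant_pop_mean[g$truth$true_pop > 0] <-
      (obs_d * tab$censused_area_km2)[g$truth$true_pop > 0]
    r2 <- tab[keep, ]
    d_obs <- obs_d[keep]
    naive[r] <- coef(lm(
      log(r2$visits) ~ log(r2$area_km2) + d_obs + r2$forest +
        I(d_obs * r2$forest) + r2$lion + r2$natural_attractiveness +
        log(r2$nearby_population) + log(r2$accessibility_minutes) +
        log(r2$country_ppp)))["d_obs"]
    fit <- fit_visitation_model(tab, quick_config(iters = 400,
                                                  seed = 50 + r))
    eiv[r] <- coef_summary(fit)[3, "mean"]
  }
  expect_lt(mean(abs(naive)), mean(abs(eiv)))
})

test_that("split R-hat and ESS behave on known chain configurations", {
  set.seed(5)
  mk_fit <- function(draws_per_chain, shift = 0) {
    x <- c(rnorm(draws_per_chain), rnorm(draws_per_chain) + shift,
           rnorm(draws_per_chain), rnorm(draws_per_chain))
    draws <- cbind(elephant_density = x, sigma = abs(x) + 1)
    poachval:::new_visitation_fit(
      draws, chain = rep(1:4, each = draws_per_chain),
      mean_row = c(intercept = 1), density = NULL,
      terms = "elephant_density", seed = 1L)
  }
  conv <- check_convergence(mk_fit(2000), pipeline_config())
  expect_true(all(conv$parameters$rhat >= 1 - 1e-8))
  expect_true(all(conv$parameters$rhat <= 1.01))
  expect_true(all(conv$parameters$ess >= 400))
  expect_true(conv$pass)

  # chains with disjoint supports: R-hat far above the threshold
  bad <- check_convergence(mk_fit(500, shift = 50), pipeline_config())
  expect_gt(max(bad$parameters$rhat), 1.5)
  expect_false(bad$pass)

  single <- mk_fit(100)
  single$chain <- rep(1L, nrow(single$draws))
  single$n_chains <- 1L
  expect_error(check_convergence(single, pipeline_config()),
               "at least 2 chains")
})

test_that("the within-site model recovers its coefficients", {
  pan <- generate_within_site_panel(n_years = 56, seed = 23)
  fit <- fit_within_site(pan, config = quick_config(iters = 800, seed = 4))
  s <- coef_summary(fit)
  bd <- s[s$parameter == "elephant_density", ]
  expect_lt(bd$q2.5, 0.67)
  expect_gt(bd$q97.5, 0.67)

  # near-zero noise: tight recovery of all coefficients
  pan0 <- generate_within_site_panel(n_years = 40, residual_sd = 0.001,
                                     seed = 6)
  f0 <- fit_within_site(pan0, config = quick_config(iters = 600, seed = 5))
  s0 <- coef_summary(f0)
  expect_equal(s0[s0$parameter == "elephant_density", "mean"], 0.67,
               tolerance = 0.05)
  expect_equal(s0[s0$parameter == "log_area", "mean"], 0.47,
               tolerance = 0.05)

  # density-only reduced model for short series
  fd <- fit_within_site(pan[1:15, ], predictors = "density",
                        config = quick_config(iters = 400, seed = 7))
  expect_setequal(fd$terms, c("intercept", "elephant_density"))

  # collinear design is rejected before sampling
  flat <- pan
  flat$area_km2 <- 100
  expect_error(fit_within_site(flat, predictors = c("area", "density"),
                               config = quick_config(iters = 100)),
               "collinear")
})
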