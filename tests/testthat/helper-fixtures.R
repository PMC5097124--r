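# shared fixtures: tiny PA tables built in code, quick MCMC configs

# a small, fully valid PA table with a mix of uncertainty forms
tiny_pa_table <- function(n = 6) {
  base <- data.frame(
    pa_id = sprintf("T%03d", seq_len(n)),
    name = paste("Test PA", seq_len(n)),
    country = "CountryX",
    region = rep(c("east", "south", "west", "central"), length.out = n),
    iucn_category = rep(c("II", "IV", "VI"), length.out = n),
    area_km2 = seq(100, 100 * n, by = 100),
    visits = seq(1000, 1000 * n, by = 1000),
    elephant_pop_mean = c(2000, 500, 0, 1500, 800, 3000)[seq_len(n)],
    elephant_pop_sd = c(300, NA, NA, NA, 150, NA)[seq_len(n)],
    elephant_pop_lo = c(NA, 300, NA, NA, NA, 2000)[seq_len(n)],
    elephant_pop_hi = c(NA, 700, NA, NA, NA, 4000)[seq_len(n)],
    censused_area_km2 = seq(100, 100 * n, by = 100),
    forest = rep(c(FALSE, TRUE), length.out = n),
    lion = rep(c(TRUE, FALSE), length.out = n),
    natural_attractiveness = rep(c(3, 4, 5), length.out = n),
    nearby_population = rep(5e4, n),
    accessibility_minutes = rep(240, n),
    country_ppp = rep(5000, n),
    poach_decline_rate = rep(0.05, n),
    current_spend_km2 = NA_real_,
    stringsAsFactors = FALSE)
  base
}

# quick MCMC configuration for unit tests
quick_config <- function(chains = 2, iters = 500, seed = 1,
                         n_draws = 2000) {
  pipeline_config(mcmc = list(chains = chains, warmup_iters = iters,
                              sampling_iters = iters, seed = seed),
                  valuation = list(n_draws = n_draws, seed = seed))
}

# a degenerate single-draw "fit" with coefficients fixed by the test,
# for closed-form checks of the prediction arithmetic
degenerate_fit <- function(intercept = log(1000), b_density = 0,
                           b_interaction = 0, n_draws = 1) {
  terms <- c("intercept", "log_area", "elephant_density", "forest",
             "density_x_forest", "lion", "natural_attractiveness",
             "log_nearby_population", "log_accessibility",
             "log_country_ppp")
  draws <- matrix(0, nrow = n_draws, ncol = length(terms) + 1,
                  dimnames = list(NULL, c(terms, "sigma")))
  draws[, "intercept"] <- intercept
  draws[, "elephant_density"] <- b_density
  draws[, "density_x_forest"] <- b_interaction
  draws[, "sigma"] <- 0.1
  mean_row <- stats::setNames(rep(0, 8),
    c("intercept", "log_area", "forest", "lion", "natural_attractiveness",
      "log_nearby_population", "log_accessibility", "log_country_ppp"))
  mean_row["intercept"] <- 1
  poachval:::new_visitation_fit(draws, chain = rep(1L, n_draws),
                                mean_row = mean_row, density = NULL,
                                terms = terms, seed = 0L)
}

# counterfactual-results data frame built directly
loss_table <- function(visit_loss, region = "east",
                       pa_id = sprintf("L%03d", seq_along(visit_loss))) {
  data.frame(pa_id = pa_id, region = rep(region,
                                         length.out = length(visit_loss)),
             visit_loss = visit_loss, stringsAsFactors = FALSE)
}
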