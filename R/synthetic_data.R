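#' Parameters for the synthetic study-design generator
#'
#' Defaults reproduce the structure of the study's fitting data: 216 PAs
#' harbouring elephants plus 54 elephant-free PAs with visitor data, 164 PAs
#' with visits in total, 55% of elephant populations carrying an uncertainty
#' estimate (43% as an sd, 12% as a range, remainder missing), and 58 PAs
#' forced above 1,000 elephants.  Visits are generated from the log-linear
#' visitation model itself, using the latent (true) elephant density, so that
#' fitting the model to generated tables is a genuine parameter-recovery
#' exercise.
#'
#' @param n_pas number of PAs with elephants.
#' @param n_no_elephant number of additional elephant-free PAs with visitor
#'   data.
#' @param n_with_visits total number of PAs (elephant + elephant-free) with
#'   observed visits; must be >= `n_no_elephant`.
#' @param true_coefficients named vector on the analysis scale of
#'   [build_design()]: `intercept`, `log_area`, `elephant_density`, `forest`,
#'   `density_x_forest`, `lion`, `natural_attractiveness`,
#'   `log_nearby_population`, `log_accessibility`, `log_country_ppp`.
#' @param residual_sd sd of the log-visits noise.
#' @param frac_sd_form,frac_range_form fractions of elephant populations whose
#'   uncertainty is reported as an sd / as a 95% range (sum <= 1; the
#'   remainder have no uncertainty estimate).
#' @param frac_large_pop fraction of elephant PAs forced above 1,000 animals.
#' @param sd_intercept,sd_slope,sd_jitter the population-size uncertainty
#'   rule: sd = `sd_intercept` + `sd_slope` * population, plus Gaussian jitter
#'   with sd `sd_jitter`.  Defaults match the empirical mean--sd relation the
#'   imputation sub-model assumes (192 + 0.122 x mean).
#' @param pike_range range of the annual proportional poaching loss rate.
#' @param seed integer seed; the generator is a pure function of its
#'   parameters.
#' @return A validated parameter list of class `"synthetic_params"`.
#' @export
synthetic_params <- function(n_pas = 216L,
                             n_no_elephant = 54L,
                             n_with_visits = 164L,
                             true_coefficients = c(
                               intercept = 7.2,
                               log_area = -0.3,
                               elephant_density = 1.55,
                               forest = -1.26,
                               density_x_forest = -2.02,
                               lion = 1.0,
                               natural_attractiveness = -0.18,
                               log_nearby_population = -0.1,
                               log_accessibility = -0.3,
                               log_country_ppp = 0.5),
                             residual_sd = 1.5,
                             frac_sd_form = 0.43,
                             frac_range_form = 0.12,
                             frac_large_pop = 58 / 216,
                             sd_intercept = 192,
                             sd_slope = 0.122,
                             sd_jitter = 25,
                             pike_range = c(0.0, 0.10),
                             seed = 1L) {
  p <- list(n_pas = as.integer(n_pas),
            n_no_elephant = as.integer(n_no_elephant),
            n_with_visits = as.integer(n_with_visits),
            true_coefficients = true_coefficients,
            residual_sd = residual_sd,
            frac_sd_form = frac_sd_form, frac_range_form = frac_range_form,
            frac_large_pop = frac_large_pop,
            sd_intercept = sd_intercept, sd_slope = sd_slope,
            sd_jitter = sd_jitter,
            pike_range = pike_range, seed = as.integer(seed))
  if (p$n_pas <= 0) stop("n_pas must be > 0", call. = FALSE)
  if (p$frac_sd_form + p$frac_range_form > 1)
    stop("frac_sd_form + frac_range_form must be <= 1", call. = FALSE)
  if (p$residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  if (p$n_with_visits < p$n_no_elephant ||
      p$n_with_visits > p$n_pas + p$n_no_elephant)
    stop("n_with_visits must lie in [n_no_elephant, n_pas + n_no_elephant]",
         call. = FALSE)
  need <- c("intercept", "log_area", "elephant_density", "forest",
            "density_x_forest", "lion", "natural_attractiveness",
            "log_nearby_population", "log_accessibility", "log_country_ppp")
  miss <- setdiff(need, names(p$true_coefficients))
  if (length(miss))
    stop("true_coefficients missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(p) <- c("synthetic_params", "list")
  p
}

rtrunc_norm <- function(n, mean, sd, lower) {
  # inverse-cdf draw from Normal(mean, sd) truncated below at `lower`;
  # sd may be a vector; sd == 0 collapses to max(mean, lower)
  sd <- rep_len(sd, n); mean <- rep_len(mean, n)
  out <- pmax(mean, lower)
  pos <- sd > 0
  if (any(pos)) {
    a <- stats::pnorm(lower, mean[pos], sd[pos])
    u <- stats::runif(sum(pos))
    out[pos] <- stats::qnorm(a + u * (1 - a), mean[pos], sd[pos])
    # guard against qnorm(1) overflow at extreme truncation
    out[pos][!is.finite(out[pos])] <- lower
  }
  out
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Generate a synthetic PA table with a latent-truth companion
#'
#' Covariates are drawn from fixed, realistic marginals (area and the other
#' scale covariates log-uniform, forest Bernoulli(0.25), lion Bernoulli(0.6),
#' attractiveness uniform on 1–5, latent elephant density uniform on (0, 2)
#' km^-2 where elephants are present).  The reported population mean relates
#' to the latent true population through a symmetric normal measurement with
#' the record's own sd: the truth is drawn as a zero-truncated normal about
#' the report, the same observation relation the fitted model assumes, so
#' credible-interval coverage of generated tables is a meaningful calibration
#' check.  Range-form records report `mean -/+ 1.96 sd` as a 95% interval.
#'
#' @param params a [synthetic_params()] list.
#' @return list with `pa` (a PA table, see [pa_table]) and `truth` (one row
#'   per PA: `pa_id`, `true_density`, `true_pop`, `true_sd`, `linear_pred`,
#'   `has_visits`).
#' @export
generate_pa_table <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  ne <- params$n_pas
  nz <- params$n_no_elephant
  n <- ne + nz
  b <- params$true_coefficients

  pa_id <- sprintf("PA%04d", seq_len(n))
  region <- sample(pa_regions, n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2))
  forest <- stats::runif(n) < 0.25
  lion <- stats::runif(n) < 0.6
  attract <- sample(1:5, n, replace = TRUE)
  nearby <- runif_log(n, 1e3, 1e6)
  access <- runif_log(n, 30, 3000)
  ppp <- runif_log(n, 500, 2e4)
  iucn <- sample(pa_iucn_ok, n, replace = TRUE,
                 prob = c(0.4, 0.1, 0.25, 0.1, 0.15))
  pike <- stats::runif(n, params$pike_range[1], params$pike_range[2])

  # areas & reported densities: `n_large` elephant PAs are forced > 1,000
  # reported animals, the rest are capped below the threshold
  n_large <- round(params$frac_large_pop * ne)
  is_large <- c(seq_len(ne) %in% sample.int(ne, n_large), rep(FALSE, nz))
  area <- numeric(n)
  drep <- numeric(n)
  for (i in seq_len(n)) {
    if (i > ne) {            # elephant-free PA
      area[i] <- runif_log(1, 10, 1e4); drep[i] <- 0
    } else if (is_large[i]) {
      area[i] <- runif_log(1, 1000, 1e4)
      drep[i] <- stats::runif(1, 1.05 * 1000 / area[i], 2)
    } else {
      area[i] <- runif_log(1, 10, 1e4)
      drep[i] <- stats::runif(1, 0, min(2, 999 / area[i]))
    }
  }
  censused <- area
  obs_mean <- drep * censused
  true_sd <- pmax(1, params$sd_intercept + params$sd_slope * obs_mean +
                       stats::rnorm(n, 0, params$sd_jitter))
  true_sd[obs_mean == 0] <- 0

  # latent true population: reported mean is a symmetric-normal measurement
  # of the truth, so the truth is drawn about the report (zero-truncated),
  # exactly the observation relation the fitted model assumes
  true_pop <- ifelse(obs_mean > 0,
                     rtrunc_norm(n, obs_mean, true_sd, 0), 0)
  dens <- true_pop / censused

  # uncertainty-form assignment among elephant PAs
  n_sd <- round(params$frac_sd_form * ne)
  n_rng <- round(params$frac_range_form * ne)
  form <- rep("none", n)
  elev <- sample.int(ne)                    # random assignment among PAs 1..ne
  form[elev[seq_len(n_sd)]] <- "sd"
  if (n_rng > 0) form[elev[n_sd + seq_len(n_rng)]] <- "range"
  form[(ne + 1):n] <- "zero"
  z975 <- stats::qnorm(0.975)
  pop_sd <- ifelse(form == "sd", true_sd, NA_real_)
  pop_lo <- ifelse(form == "range", pmax(0, obs_mean - z975 * true_sd),
                   NA_real_)
  pop_hi <- ifelse(form == "range", obs_mean + z975 * true_sd, NA_real_)

  # visits from the log-linear model at the *latent* density
  lp <- b["intercept"] + b["log_area"] * log(area) +
    b["elephant_density"] * dens + b["forest"] * forest +
    b["density_x_forest"] * dens * forest + b["lion"] * lion +
    b["natural_attractiveness"] * attract +
    b["log_nearby_population"] * log(nearby) +
    b["log_accessibility"] * log(access) +
    b["log_country_ppp"] * log(ppp)
  lp <- as.numeric(lp)
  visits_all <- exp(lp + stats::rnorm(n, 0, params$residual_sd))
  n_vis_ele <- params$n_with_visits - nz
  has_visits <- c(seq_len(ne) %in% sample.int(ne, n_vis_ele), rep(TRUE, nz))
  visits <- ifelse(has_visits, visits_all, NA_real_)

  pa <- data.frame(
    pa_id = pa_id,
    name = paste("Synthetic PA", seq_len(n)),
    country = paste0("Country", toupper(substr(region, 1, 1))),
    region = region,
    iucn_category = iucn,
    area_km2 = area,
    visits = visits,
    elephant_pop_mean = obs_mean,
    elephant_pop_sd = pop_sd,
    elephant_pop_lo = pop_lo,
    elephant_pop_hi = pop_hi,
    censused_area_km2 = censused,
    forest = forest,
    lion = lion,
    natural_attractiveness = as.numeric(attract),
    nearby_population = nearby,
    accessibility_minutes = access,
    country_ppp = ppp,
    poach_decline_rate = pike,
    current_spend_km2 = NA_real_,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(pa_id = pa_id, true_density = dens, true_pop = true_pop,
                      true_sd = true_sd, linear_pred = lp,
                      has_visits = has_visits, stringsAsFactors = FALSE)
  list(pa = validate_pa_table(pa), truth = truth)
}

#' Generate synthetic spend and multiplier estimate sets
#'
#' Direct per-visit expenditures are i.i.d. exponential with the given mean;
#' multipliers are Gaussian truncated below at 1 (a total-impact multiplier
#' cannot be smaller than the direct spend it multiplies).
#'
#' @param n_direct,n_mult numbers of estimates (study design: 36 and 24).
#' @param direct_mean mean per-visit expenditure, USD.
#' @param mult_mean,mult_sd multiplier Gaussian parameters before truncation.
#' @param seed integer seed.
#' @return A `"spend_estimates"` list (see [spend_estimates()]).
#' @export
generate_spend_estimates <- function(n_direct = 36L, n_mult = 24L,
                                     direct_mean = 200, mult_mean = 2.8,
                                     mult_sd = 0.8, seed = 1L) {
  if (n_direct <= 0 || n_mult <= 0)
    stop("n_direct and n_mult must be > 0", call. = FALSE)
  if (direct_mean <= 0) stop("direct_mean must be > 0", call. = FALSE)
  if (mult_sd < 0) stop("mult_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  direct <- stats::rexp(n_direct, rate = 1 / direct_mean)
  mult <- rtrunc_norm(n_mult, mult_mean, mult_sd, 1)
  suppressMessages(spend_estimates(direct, mult))
}

#' Generate a single-site visitation time series
#'
#' Emulates a long within-site panel (the study's Addo-style comparison):
#' park area and national GDP grow smoothly over the years, elephant density
#' recovers from near zero towards a carrying density, and visits follow the
#' reduced log-linear model `log(visits) = b0 + b_area log(area) +
#' b_gdp log(gdp) + b_density density + noise`.
#'
#' @param n_years panel length (>= 10; the study series spans 56 years).
#' @param true_coefficients named vector `intercept`, `log_area`, `log_gdp`,
#'   `elephant_density`.
#' @param residual_sd sd of log-visits noise.
#' @param seed integer seed.
#' @return data frame with `year`, `visits`, `area_km2`, `country_gdp`,
#'   `elephant_density`.
#' @export
generate_within_site_panel <- function(n_years = 56L,
                                       true_coefficients = c(
                                         intercept = 10.91,
                                         log_area = 0.47,
                                         log_gdp = -0.46,
                                         elephant_density = 0.67),
                                       residual_sd = 0.38,
                                       seed = 1L) {
  if (n_years < 10) stop("n_years must be >= 10", call. = FALSE)
  need <- c("intercept", "log_area", "log_gdp", "elephant_density")
  miss <- setdiff(need, names(true_coefficients))
  if (length(miss))
    stop("true_coefficients missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  b <- true_coefficients
  year <- seq(1955L, by = 1L, length.out = n_years)
  t01 <- seq(0, 1, length.out = n_years)
  area <- exp(log(50) + t01 * (log(400) - log(50))) *
    exp(stats::rnorm(n_years, 0, 0.02))
  gdp <- exp(log(1500) + t01 * (log(9000) - log(1500))) *
    exp(stats::rnorm(n_years, 0, 0.03))
  dens <- pmax(0.02, 0.1 + 1.9 * t01 + stats::rnorm(n_years, 0, 0.05))
  lp <- b["intercept"] + b["log_area"] * log(area) + b["log_gdp"] * log(gdp) +
    b["elephant_density"] * dens
  visits <- exp(as.numeric(lp) + stats::rnorm(n_years, 0, residual_sd))
  data.frame(year = year, visits = visits, area_km2 = area,
             country_gdp = gdp, elephant_density = dens)
}
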