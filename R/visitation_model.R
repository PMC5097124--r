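#' Convert a population range to a normal mean and sd
#'
#' A range-form uncertainty report is interpreted as a 95% interval of a
#' normal distribution centred at the midpoint, so `mean = (lo + hi) / 2` and
#' `sd = (hi - lo) / (2 * z)` with `z = qnorm(0.975) = 1.959964`.
#'
#' @param lo,hi nonnegative range endpoints, `lo <= hi` (vectorised).
#' @return data frame with columns `mean` and `sd`.
#' @examples
#' range_to_normal(800, 1200)  # mean 1000, sd 102.04
#' @export
range_to_normal <- function(lo, hi) {
  if (length(lo) != length(hi))
    stop("lo and hi must have equal length", call. = FALSE)
  if (any(lo > hi)) stop("range lo must be <= hi", call. = FALSE)
  z <- stats::qnorm(0.975)
  data.frame(mean = (lo + hi) / 2, sd = (hi - lo) / (2 * z))
}

#' Parameters of the population-sd imputation line
#'
#' Missing population-size standard deviations are imputed from the strong
#' empirical linear relation between reported sds and population means,
#' `sd = 192 + 0.122 * mean`.
#'
#' @param intercept,slope the line's parameters (USD of elephants, i.e.
#'   animals); `slope >= 0`.
#' @param residual_sd residual scale of the relation; `NULL` (default) lets
#'   [fit_visitation_model()] estimate it in-model from the sd-form records.
#' @return list of class `"imputation_params"`.
#' @export
imputation_params <- function(intercept = 192, slope = 0.122,
                              residual_sd = NULL) {
  if (slope < 0) stop("imputation slope must be >= 0", call. = FALSE)
  structure(list(intercept = intercept, slope = slope,
                 residual_sd = residual_sd),
            class = c("imputation_params", "list"))
}

#' Point imputation of a missing population sd
#'
#' The deterministic (point) form of the imputation line; within
#' [fit_visitation_model()] the same line is used stochastically, with the
#' missing sd treated as a parameter centred on it.
#'
#' @param mean nonnegative population mean (vectorised).
#' @param params an [imputation_params()] list.
#' @return Imputed sd(s).
#' @examples
#' impute_population_sd(10000)  # 1412
#' @export
impute_population_sd <- function(mean, params = imputation_params()) {
  if (any(mean < 0)) stop("population mean must be >= 0", call. = FALSE)
  params$intercept + params$slope * mean
}

# analysis-scale design columns, in reporting order
design_terms <- c("intercept", "log_area", "elephant_density", "forest",
                  "density_x_forest", "lion", "natural_attractiveness",
                  "log_nearby_population", "log_accessibility",
                  "log_country_ppp")
# fixed-covariate columns (everything except the latent density terms)
fixed_terms <- setdiff(design_terms, c("elephant_density",
                                       "density_x_forest"))

#' Build the visitation design from PA records
#'
#' Restricts to records with observed visits, takes `log(visits)` as the
#' response, log-transforms the scale covariates (area, nearby population,
#' accessibility, country PPP) and assembles the elephant-density observation
#' model: density mean and sd are the population mean and sd divided by the
#' censused area, with range-form records first converted by
#' [range_to_normal()].  Records without elephants enter with density fixed
#' at zero; records without an uncertainty estimate are flagged for in-model
#' imputation.
#'
#' @param records validated PA table.
#' @return list with `y` (log visits), `X` (matrix of fixed covariates,
#'   intercept first), `density` (data frame `pa_id`, `form`, `mean`, `sd`,
#'   `pop_mean`, `censused_area`), `forest` (logical vector) and `pa_id`.
#' @export
build_design <- function(records) {
  records <- validate_pa_table(records)
  keep <- !is.na(records$visits)
  r <- records[keep, , drop = FALSE]
  if (any(r$visits <= 0)) {
    bad <- r$pa_id[r$visits <= 0][1]
    stop("cannot log-transform visits <= 0 at PA '", bad, "'", call. = FALSE)
  }
  y <- log(r$visits)
  X <- cbind(intercept = 1,
             log_area = log(r$area_km2),
             forest = as.numeric(r$forest),
             lion = as.numeric(r$lion),
             natural_attractiveness = r$natural_attractiveness,
             log_nearby_population = log(r$nearby_population),
             log_accessibility = log(r$accessibility_minutes),
             log_country_ppp = log(r$country_ppp))
  X <- X[, fixed_terms, drop = FALSE]

  form <- pa_uncertainty_form(r)
  dmean <- rep(0, nrow(r))
  dsd <- rep(NA_real_, nrow(r))
  pres <- form != "zero"
  dmean[pres] <- r$elephant_pop_mean[pres] / r$censused_area_km2[pres]
  sdf <- form == "sd"
  dsd[sdf] <- r$elephant_pop_sd[sdf] / r$censused_area_km2[sdf]
  rng <- form == "range"
  if (any(rng)) {
    conv <- range_to_normal(r$elephant_pop_lo[rng], r$elephant_pop_hi[rng])
    dmean[rng] <- conv$mean / r$censused_area_km2[rng]
    dsd[rng] <- conv$sd / r$censused_area_km2[rng]
  }
  # a reported sd of (numerically) zero is an exact observation
  exact <- pres & !is.na(dsd) & dsd < 1e-10
  form[exact] <- "exact"
  list(y = y,
       X = X,
       density = data.frame(pa_id = r$pa_id, form = form, mean = dmean,
                            sd = dsd,
                            pop_mean = ifelse(pres, r$elephant_pop_mean, 0),
                            pop_sd = r$elephant_pop_sd,
                            censused_area = r$censused_area_km2,
                            stringsAsFactors = FALSE),
       forest = r$forest,
       pa_id = r$pa_id)
}

#' Percent change in visits per unit change of a log-linear predictor
#'
#' The semi-elasticity of a log-linear model: `100 * (exp(beta) - 1)`.
#'
#' @param beta coefficient on the analysis scale.
#' @return Percent change.
#' @examples
#' effect_size_percent(1.55)  # ~371%
#' @export
effect_size_percent <- function(beta) 100 * (exp(beta) - 1)

#' Additional annual visits from a small density increase
#'
#' Linear scaling of the per-unit semi-elasticity at a baseline visit count:
#' `median_visits * delta_density * (exp(beta) - 1)`.
#'
#' @param median_visits baseline annual visits (> 0).
#' @param beta density coefficient.
#' @param delta_density density increase, elephants km^-2.
#' @return Additional annual visits.
#' @examples
#' marginal_visits(1883, 1.55, 0.1)  # ~700
#' @export
marginal_visits <- function(median_visits, beta, delta_density) {
  if (any(median_visits <= 0))
    stop("median_visits must be > 0", call. = FALSE)
  median_visits * delta_density * (exp(beta) - 1)
}
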