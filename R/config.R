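#' Pipeline configuration
#'
#' Builds the nested configuration list consumed by [fit_visitation_model()],
#' [simulate_valuation()], [cost_assessment()] and [run_pipeline()].  Defaults
#' correspond to the study design: four MCMC chains, a 100,000-draw valuation,
#' the $215 km^-2 (USD 1981) anti-poaching benchmark inflated to $565 km^-2
#' (USD 2016), and a 1,000-elephant threshold for the cost assessment.
#'
#' @param mcmc_scale `"test"` (4 chains of 1,000 sampling iterations after
#'   1,000 warmup; minutes on a laptop) or `"paper"` (4 chains of 25,000 after
#'   25,000 warmup, the scale used for the published estimates).  Individual
#'   entries of `mcmc` override the scale.
#' @param mcmc list with `chains`, `warmup_iters`, `sampling_iters`, `thin`,
#'   `seed`.
#' @param priors list with `coef_sd` (normal prior sd on standardized-scale
#'   coefficients) and `sigma_scale` (half-normal prior scale on the residual
#'   sd of log visits).
#' @param valuation list with `n_draws` and `seed` for the Monte Carlo
#'   monetisation.
#' @param cost list with `benchmark_1981_usd`, `inflation_factor`, `slope_b`,
#'   `large_pop_threshold`; see [cost_params()].
#' @param transforms character vector of predictor columns entered on the
#'   natural-log scale.
#' @param convergence list with `rhat_max` and `ess_min`.
#' @return A list of class `"pipeline_config"`.
#' @seealso [read_config()]
#' @examples
#' cfg <- pipeline_config(mcmc = list(chains = 2, seed = 7))
#' cfg$mcmc$chains
#' @export
pipeline_config <- function(mcmc_scale = c("test", "paper"),
                            mcmc = list(),
                            priors = list(),
                            valuation = list(),
                            cost = list(),
                            transforms = NULL,
                            convergence = list()) {
  mcmc_scale <- match.arg(mcmc_scale)
  iters <- if (mcmc_scale == "paper") 25000L else 1000L
  cfg <- list(
    mcmc = list(chains = 4L, warmup_iters = iters, sampling_iters = iters,
                thin = 1L, seed = 1L),
    priors = list(coef_sd = 10, sigma_scale = 5),
    valuation = list(n_draws = 100000L, seed = 1L),
    cost = list(benchmark_1981_usd = 215, inflation_factor = 565 / 215,
                slope_b = 0.05, large_pop_threshold = 1000),
    transforms = c("area_km2", "nearby_population", "accessibility_minutes",
                   "country_ppp"),
    convergence = list(rhat_max = 1.01, ess_min = 400)
  )
  cfg$mcmc <- utils::modifyList(cfg$mcmc, mcmc)
  cfg$priors <- utils::modifyList(cfg$priors, priors)
  cfg$valuation <- utils::modifyList(cfg$valuation, valuation)
  cfg$cost <- utils::modifyList(cfg$cost, cost)
  if (!is.null(transforms)) cfg$transforms <- transforms
  cfg$convergence <- utils::modifyList(cfg$convergence, convergence)
  validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

validate_config <- function(cfg) {
  m <- cfg$mcmc
  if (m$chains < 2) stop("config: mcmc$chains must be >= 2", call. = FALSE)
  if (m$warmup_iters <= 0 || m$sampling_iters <= 0)
    stop("config: mcmc iteration counts must be > 0", call. = FALSE)
  if (cfg$valuation$n_draws <= 0)
    stop("config: valuation$n_draws must be > 0", call. = FALSE)
  if (cfg$cost$large_pop_threshold < 0)
    stop("config: cost$large_pop_threshold must be >= 0", call. = FALSE)
  if (cfg$convergence$rhat_max < 1)
    stop("config: convergence$rhat_max must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The document mirrors the structure of [pipeline_config()]; keys omitted
#' from the file keep their defaults.
#'
#' @param path path to a `.yml`/`.yaml` or `.json` file.
#' @return A `"pipeline_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, c(
    list(mcmc_scale = raw$mcmc_scale %||% "test"),
    raw[intersect(names(raw),
                  c("mcmc", "priors", "valuation", "cost", "transforms",
                    "convergence"))]
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
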