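# Fitting the Bayesian errors-in-variables visitation model with JAGS.
#
# The linear predictor for log annual visits is
#   mu_i = X_i beta + (b_d + b_int * forest_i) * d_i
# where d_i is the latent elephant density (km^-2).  Densities observed with
# an sd (reported or range-derived) get a truncated-normal observation model;
# densities with no uncertainty estimate get an sd imputed in-model from the
# empirical line sd = 192 + 0.122 * mean (population scale), whose residual
# scale is informed by the sd-form records; PAs without elephants enter with
# d_i fixed at zero.  Continuous fixed covariates are standardized internally
# for sampler stability and coefficients are reported back on the analysis
# scale of build_design().

scale_cols <- c("log_area", "natural_attractiveness",
                "log_nearby_population", "log_accessibility",
                "log_country_ppp")

new_visitation_fit <- function(draws, chain, mean_row, density, terms,
                               seed, config = NULL, standardization = NULL) {
  structure(list(draws = draws, chain = as.integer(chain),
                 n_chains = length(unique(chain)),
                 n_per_chain = as.integer(sum(chain == chain[1])),
                 mean_row = mean_row, density = density, terms = terms,
                 seed = seed, config = config,
                 standardization = standardization),
            class = c("visitation_fit", "list"))
}

jags_seed_inits <- function(chains, seed) {
  lapply(seq_len(chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(seed) %% 1000000L) * 1000L + k))
}

run_jags <- function(model_string, data, monitors, config) {
  m <- config$mcmc
  adapt <- max(100L, ceiling(m$warmup_iters / 2))
  burn <- max(0L, m$warmup_iters - adapt)
  jm <- tryCatch(
    rjags::jags.model(textConnection(model_string), data = data,
                      n.chains = m$chains, n.adapt = adapt, quiet = TRUE,
                      inits = jags_seed_inits(m$chains, m$seed)),
    error = function(e) stop("MCMC initialisation failed: ",
                             conditionMessage(e), call. = FALSE))
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  tryCatch(
    rjags::coda.samples(jm, monitors, n.iter = m$sampling_iters,
                        thin = m$thin, progress.bar = "none"),
    error = function(e) stop("MCMC sampling failed: ", conditionMessage(e),
                             call. = FALSE))
}

# stack an mcmc.list into (matrix, chain index)
stack_chains <- function(samples) {
  mats <- lapply(samples, as.matrix)
  draws <- do.call(rbind, mats)
  chain <- rep(seq_along(mats), vapply(mats, nrow, 0L))
  list(draws = draws, chain = chain)
}

#' Fit the Bayesian errors-in-variables visitation model
#'
#' Samples the joint posterior of the regression coefficients, the residual
#' sd of log visits, the latent per-PA elephant densities and any imputed
#' population sds, using MCMC (JAGS).  Priors are vague: Normal(0, `coef_sd`^2)
#' on standardized-scale coefficients and half-Normal(0, `sigma_scale`) on
#' the residual sd.  Runs are reproducible: the same configuration and seed
#' give identical draws.
#'
#' @param records validated PA table; at least 20 rows must have observed
#'   visits.
#' @param config a [pipeline_config()] list (`mcmc` and `priors` entries are
#'   used).
#' @param imp an [imputation_params()] list; its `residual_sd`, when given,
#'   fixes the imputation line's residual scale instead of estimating it.
#' @return A `"visitation_fit"` object: `draws` (posterior draws on the
#'   analysis scale, one column per parameter: the ten design coefficients,
#'   `sigma`, `sigma_imp` (when estimated), `density[pa_id]` latents and
#'   `pop_sd[pa_id]` imputed sds), `chain`, the covariate `mean_row` used for
#'   at-means prediction, and the density observation table.
#' @export
fit_visitation_model <- function(records, config = pipeline_config(),
                                 imp = imputation_params()) {
  des <- build_design(records)
  n <- length(des$y)
  if (n < 20)
    stop("need at least 20 records with observed visits, got ", n,
         call. = FALSE)
  X <- des$X
  ctr <- sc <- stats::setNames(rep(0, ncol(X)), colnames(X))
  sc[] <- 1
  for (cc in intersect(scale_cols, colnames(X))) {
    ctr[cc] <- mean(X[, cc]); sc[cc] <- stats::sd(X[, cc])
    if (sc[cc] == 0) sc[cc] <- 1
    X[, cc] <- (X[, cc] - ctr[cc]) / sc[cc]
  }

  form <- des$density$form
  iobs <- which(form %in% c("sd", "range"))
  imis <- which(form == "none")
  d_data <- rep(NA_real_, n)
  d_data[form == "zero"] <- 0
  d_data[form == "exact"] <- des$density$mean[form == "exact"]

  sdrec <- des$density$form == "sd"
  est_imp <- is.null(imp$residual_sd)
  data <- list(y = des$y, Xs = X, P = ncol(X), N = n,
               forest = as.numeric(des$forest), d = d_data,
               coef_prec = 1 / config$priors$coef_sd^2,
               sigma_prec = 1 / config$priors$sigma_scale^2)

  blocks <- c(
    "model {",
    "  for (j in 1:P) { beta[j] ~ dnorm(0, coef_prec) }",
    "  bd ~ dnorm(0, coef_prec)",
    "  bint ~ dnorm(0, coef_prec)",
    "  sigma ~ dnorm(0, sigma_prec) T(0,)",
    "  tau <- pow(sigma, -2)",
    "  for (i in 1:N) {",
    "    y[i] ~ dnorm(mu[i], tau)",
    "    mu[i] <- inprod(Xs[i,], beta) + bd * d[i] + bint * d[i] * forest[i]",
    "  }")
  monitors <- c("beta", "bd", "bint", "sigma")
  if (length(iobs)) {
    data$iobs <- iobs
    data$dmean <- des$density$mean[iobs]
    data$dprec <- des$density$sd[iobs]^-2
    data$Nobs <- length(iobs)
    blocks <- c(blocks,
      "  for (k in 1:Nobs) { d[iobs[k]] ~ dnorm(dmean[k], dprec[k]) T(0,) }")
  }
  if (length(imis)) {
    data$imis <- imis
    data$popmean <- des$density$pop_mean[imis]
    data$carea <- des$density$censused_area[imis]
    data$Nmis <- length(imis)
    data$imp_a <- imp$intercept
    data$imp_b <- imp$slope
    blocks <- c(blocks,
      "  for (k in 1:Nmis) {",
      "    sdpop[k] ~ dnorm(imp_a + imp_b * popmean[k], tau_imp) T(1,)",
      "    d[imis[k]] ~ dnorm(popmean[k] / carea[k],",
      "                       pow(sdpop[k] / carea[k], -2)) T(0,)",
      "  }")
    monitors <- c(monitors, "sdpop")
    if (est_imp) {
      blocks <- c(blocks,
        "  sigma_imp ~ dnorm(0, pow(500, -2)) T(0,)",
        "  tau_imp <- pow(sigma_imp, -2)")
      monitors <- c(monitors, "sigma_imp")
      if (any(sdrec)) {
        data$Nsd <- sum(sdrec)
        data$sd_obs <- des$density$pop_sd[sdrec]
        data$sd_pm <- des$density$pop_mean[sdrec]
        blocks <- c(blocks,
          "  for (k in 1:Nsd) {",
          "    sd_obs[k] ~ dnorm(imp_a + imp_b * sd_pm[k], tau_imp)",
          "  }")
      }
    } else {
      data$tau_imp <- imp$residual_sd^-2
    }
  }
  if (length(iobs) || length(imis)) monitors <- c(monitors, "d")
  blocks <- c(blocks, "}")

  samples <- run_jags(paste(blocks, collapse = "\n"), data, monitors, config)
  st <- stack_chains(samples)
  raw <- st$draws

  # back-transform to the analysis scale
  p <- ncol(X)
  bcols <- paste0("beta[", seq_len(p), "]")
  if (p == 1) bcols <- "beta"
  B <- raw[, bcols, drop = FALSE]
  colnames(B) <- colnames(X)
  for (cc in intersect(scale_cols, colnames(X))) {
    B[, "intercept"] <- B[, "intercept"] - B[, cc] * ctr[cc] / sc[cc]
    B[, cc] <- B[, cc] / sc[cc]
  }
  out <- cbind(B[, "intercept", drop = FALSE],
               log_area = B[, "log_area"],
               elephant_density = raw[, "bd"],
               forest = B[, "forest"],
               density_x_forest = raw[, "bint"],
               lion = B[, "lion"],
               natural_attractiveness = B[, "natural_attractiveness"],
               log_nearby_population = B[, "log_nearby_population"],
               log_accessibility = B[, "log_accessibility"],
               log_country_ppp = B[, "log_country_ppp"],
               sigma = raw[, "sigma"])
  if ("sigma_imp" %in% colnames(raw))
    out <- cbind(out, sigma_imp = raw[, "sigma_imp"])
  dcols <- grep("^d\\[", colnames(raw))
  if (length(dcols)) {
    D <- raw[, dcols, drop = FALSE]
    idx <- as.integer(sub("^d\\[(\\d+)\\]$", "\\1", colnames(D)))
    colnames(D) <- paste0("density[", des$pa_id[idx], "]")
    out <- cbind(out, D)
  }
  scols <- grep("^sdpop\\[", colnames(raw))
  if (length(scols)) {
    S <- raw[, scols, drop = FALSE]
    k <- as.integer(sub("^sdpop\\[(\\d+)\\]$", "\\1", colnames(S)))
    colnames(S) <- paste0("pop_sd[", des$pa_id[imis[k]], "]")
    out <- cbind(out, S)
  }

  mean_row <- colMeans(des$X)        # unstandardized analysis-scale means
  new_visitation_fit(out, st$chain, mean_row, des$density, design_terms,
                     seed = config$mcmc$seed, config = config,
                     standardization = list(center = ctr, scale = sc))
}

#' Fit the reduced within-site visitation model
#'
#' A Bayesian log-linear regression of annual visits at a single site over
#' time, on (a subset of) log park area, log national GDP and elephant
#' density -- the covariates that vary within a site.  Densities are treated
#' as observed (no measurement-error component).
#'
#' @param panel data frame from [generate_within_site_panel()] or with the
#'   same columns.
#' @param predictors `c("area", "gdp", "density")` (default) or `"density"`
#'   for short series.
#' @param config a [pipeline_config()] list.
#' @return A `"visitation_fit"` object whose coefficient columns are
#'   `intercept`, `log_area`, `log_gdp` (as requested) and
#'   `elephant_density`, plus `sigma`.
#' @export
fit_within_site <- function(panel, predictors = c("area", "gdp", "density"),
                            config = pipeline_config()) {
  stopifnot(all(c("visits", "elephant_density") %in% names(panel)))
  if (nrow(panel) < 10)
    stop("need at least 10 time points, got ", nrow(panel), call. = FALSE)
  if (any(panel$visits <= 0))
    stop("cannot log-transform visits <= 0", call. = FALSE)
  predictors <- match.arg(predictors, c("area", "gdp", "density"),
                          several.ok = TRUE)
  y <- log(panel$visits)
  X <- cbind(intercept = rep(1, nrow(panel)))
  if ("area" %in% predictors) X <- cbind(X, log_area = log(panel$area_km2))
  if ("gdp" %in% predictors) X <- cbind(X, log_gdp = log(panel$country_gdp))
  if ("density" %in% predictors)
    X <- cbind(X, elephant_density = panel$elephant_density)
  if (qr(X)$rank < ncol(X))
    stop("collinear predictors in within-site design", call. = FALSE)

  Xs <- X
  ctr <- sc <- stats::setNames(rep(0, ncol(X)), colnames(X)); sc[] <- 1
  for (cc in setdiff(colnames(X), "intercept")) {
    ctr[cc] <- mean(X[, cc]); sc[cc] <- stats::sd(X[, cc])
    if (sc[cc] == 0) sc[cc] <- 1
    Xs[, cc] <- (X[, cc] - ctr[cc]) / sc[cc]
  }
  model <- paste(
    "model {",
    "  for (j in 1:P) { beta[j] ~ dnorm(0, coef_prec) }",
    "  sigma ~ dnorm(0, sigma_prec) T(0,)",
    "  tau <- pow(sigma, -2)",
    "  for (i in 1:N) { y[i] ~ dnorm(inprod(Xs[i,], beta), tau) }",
    "}", sep = "\n")
  data <- list(y = y, Xs = Xs, P = ncol(Xs), N = length(y),
               coef_prec = 1 / config$priors$coef_sd^2,
               sigma_prec = 1 / config$priors$sigma_scale^2)
  st <- stack_chains(run_jags(model, data, c("beta", "sigma"), config))
  raw <- st$draws
  B <- raw[, paste0("beta[", seq_len(ncol(Xs)), "]"), drop = FALSE]
  colnames(B) <- colnames(Xs)
  for (cc in setdiff(colnames(X), "intercept")) {
    B[, "intercept"] <- B[, "intercept"] - B[, cc] * ctr[cc] / sc[cc]
    B[, cc] <- B[, cc] / sc[cc]
  }
  out <- cbind(B, sigma = raw[, "sigma"])
  new_visitation_fit(out, st$chain, colMeans(X), density = NULL,
                     terms = colnames(X), seed = config$mcmc$seed,
                     config = config,
                     standardization = list(center = ctr, scale = sc))
}

#' @export
print.visitation_fit <- function(x, ...) {
  cat("Bayesian visitation model fit\n")
  cat("  chains:", x$n_chains, " draws/chain:", x$n_per_chain, "\n")
  cat("  parameters:", ncol(x$draws), "(incl. latent densities)\n")
  print(coef_summary(x), digits = 3)
  invisible(x)
}

#' Posterior coefficient summary in reporting layout
#'
#' One row per regression coefficient plus the residual sd: posterior mean,
#' sd, 2.5% and 97.5% quantiles, effective sample size and split R-hat.
#'
#' @param fit a `"visitation_fit"`.
#' @return data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `ess`, `rhat`.
#' @export
coef_summary <- function(fit) {
  pars <- c(intersect(fit$terms, colnames(fit$draws)), "sigma")
  d <- fit$draws[, pars, drop = FALSE]
  data.frame(
    parameter = pars,
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    q2.5 = apply(d, 2, stats::quantile, 0.025),
    q97.5 = apply(d, 2, stats::quantile, 0.975),
    ess = vapply(pars, function(p) ess_one(fit$draws[, p], fit$chain), 0),
    rhat = vapply(pars, function(p) split_rhat(fit$draws[, p], fit$chain), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Export posterior draws as a tidy table
#'
#' @param fit a `"visitation_fit"`.
#' @param parameters optional character vector of parameter names.
#' @return data frame with `chain`, `iteration`, `parameter`, `value`.
#' @export
tidy_draws <- function(fit, parameters = NULL) {
  if (is.null(parameters)) parameters <- colnames(fit$draws)
  iter <- stats::ave(seq_along(fit$chain), fit$chain, FUN = seq_along)
  do.call(rbind, lapply(parameters, function(p)
    data.frame(chain = fit$chain, iteration = iter, parameter = p,
               value = fit$draws[, p], stringsAsFactors = FALSE)))
}
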