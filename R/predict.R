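#' Posterior prediction of annual visits at a given elephant density
#'
#' For each posterior draw the linear predictor is evaluated with the fixed
#' covariates held at their fitting-sample means (on the transformed analysis
#' scale) -- or at explicitly supplied values -- plus the density effect
#' `(b_density + b_interaction * forest) * density`; predicted visits are
#' `exp(linear predictor)`, the median of the log-normal posterior
#' predictive.
#'
#' @param fit a `"visitation_fit"`.
#' @param density elephant density, km^-2 (>= 0, scalar).
#' @param forest logical; the PA's forest status, used for the
#'   density-by-forest interaction (ignored for fits without the
#'   interaction).
#' @param covariates `"means"` (default) or a named numeric vector of
#'   analysis-scale values for the fixed covariates (e.g. `log_area`);
#'   unnamed covariates keep their means.
#' @return list with `draws` (predicted visits per posterior draw) and
#'   `median`.
#' @export
predict_visits <- function(fit, density, forest = FALSE,
                           covariates = "means") {
  if (length(density) != 1 || is.na(density) || density < 0)
    stop("density must be a single nonnegative number", call. = FALSE)
  fixed <- setdiff(intersect(fit$terms, colnames(fit$draws)),
                   c("elephant_density", "density_x_forest"))
  row <- fit$mean_row[fixed]
  if (!identical(covariates, "means")) {
    if (is.null(names(covariates)))
      stop("explicit covariates must be a named vector", call. = FALSE)
    bad <- setdiff(names(covariates), fixed)
    if (length(bad))
      stop("unknown covariate(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    row[names(covariates)] <- covariates
  }
  lp <- as.vector(fit$draws[, fixed, drop = FALSE] %*% row)
  if ("elephant_density" %in% colnames(fit$draws)) {
    bint <- if ("density_x_forest" %in% colnames(fit$draws))
      fit$draws[, "density_x_forest"] else 0
    lp <- lp + (fit$draws[, "elephant_density"] +
                  bint * as.numeric(forest)) * density
  }
  draws <- exp(lp)
  list(draws = draws, median = stats::median(draws))
}

#' Observed-versus-predicted evaluation of the visitation model
#'
#' Regresses observed log visits on the median posterior-predicted log
#' visits at each fitting PA (each PA predicted with its own covariates and
#' its own latent-density draws), by ordinary least squares.
#'
#' @param fit a `"visitation_fit"` from [fit_visitation_model()].
#' @param records the PA table the model was fitted to.
#' @return list with `slope`, `intercept`, `r_squared`, and the per-PA
#'   `data` (data frame `pa_id`, `observed_log_visits`,
#'   `predicted_log_visits`).
#' @export
model_fit_r2 <- function(fit, records) {
  if (sum(!is.na(records$visits)) < 3)
    stop("need at least 3 records with observed visits", call. = FALSE)
  des <- build_design(records)
  fixed <- setdiff(intersect(fit$terms, colnames(fit$draws)),
                   c("elephant_density", "density_x_forest"))
  lp <- fit$draws[, fixed, drop = FALSE] %*% t(des$X[, fixed, drop = FALSE])
  bd <- fit$draws[, "elephant_density"]
  bint <- fit$draws[, "density_x_forest"]
  med <- numeric(length(des$y))
  for (i in seq_along(des$y)) {
    id <- des$pa_id[i]
    dcol <- paste0("density[", id, "]")
    d_i <- if (dcol %in% colnames(fit$draws)) fit$draws[, dcol]
           else des$density$mean[i]           # fixed (zero/exact) density
    med[i] <- stats::median(lp[, i] + (bd + bint * des$forest[i]) * d_i)
  }
  ols <- stats::lm(des$y ~ med)
  list(slope = unname(stats::coef(ols)[2]),
       intercept = unname(stats::coef(ols)[1]),
       r_squared = summary(ols)$r.squared,
       data = data.frame(pa_id = des$pa_id, observed_log_visits = des$y,
                         predicted_log_visits = med,
                         stringsAsFactors = FALSE))
}

#' Predicted-versus-actual scatter plot
#'
#' @param fit,records as in [model_fit_r2()].
#' @param ... passed to [graphics::plot()].
#' @return The [model_fit_r2()] result, invisibly.
#' @export
plot_predicted_vs_actual <- function(fit, records, ...) {
  r2 <- model_fit_r2(fit, records)
  graphics::plot(r2$data$predicted_log_visits, r2$data$observed_log_visits,
                 xlab = "Median predicted log visits",
                 ylab = "Observed log visits", ...)
  graphics::abline(r2$intercept, r2$slope)
  invisible(r2)
}
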