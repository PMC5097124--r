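# MCMC convergence diagnostics: split R-hat and effective sample size.

# split potential scale reduction factor: each chain is split in half and the
# usual between/within variance ratio is computed over the 2C half-chains.
split_rhat <- function(x, chain) {
  chains <- split(x, chain)
  halves <- unlist(lapply(chains, function(v) {
    n <- floor(length(v) / 2)
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  w <- mean(vars)
  if (w == 0) return(ifelse(stats::var(means) == 0, 1, Inf))
  b <- n * stats::var(means)
  sqrt((n - 1) / n + b / (w * n))
}

# effective sample size via coda on the per-chain series
ess_one <- function(x, chain) {
  ml <- coda::mcmc.list(lapply(split(x, chain), coda::mcmc))
  unname(coda::effectiveSize(ml))
}

#' Convergence report for a fitted model
#'
#' Computes split R-hat and effective sample size for every monitored
#' parameter (coefficients, residual scales, latent densities and imputed
#' sds).  Parameters with zero posterior variance (fixed by the data, e.g.
#' densities of elephant-free PAs) are excluded.  The fit passes when all
#' R-hat values are at most `rhat_max` (default 1.01) and all effective
#' sample sizes at least `ess_min`.
#'
#' @param fit a `"visitation_fit"` with at least two chains.
#' @param config a [pipeline_config()] (its `convergence` entry is used).
#' @return A `"convergence_report"`: list with `parameters` (data frame
#'   `parameter`, `rhat`, `ess`), `pass`, `rhat_max`, `ess_min`.
#' @export
check_convergence <- function(fit, config = pipeline_config()) {
  if (fit$n_chains < 2)
    stop("R-hat requires at least 2 chains", call. = FALSE)
  keep <- apply(fit$draws, 2, stats::var) > 0
  d <- fit$draws[, keep, drop = FALSE]
  rhat <- vapply(colnames(d), function(p) split_rhat(d[, p], fit$chain), 0)
  ess <- vapply(colnames(d), function(p) ess_one(d[, p], fit$chain), 0)
  pars <- data.frame(parameter = colnames(d), rhat = rhat, ess = ess,
                     row.names = NULL, stringsAsFactors = FALSE)
  rmax <- config$convergence$rhat_max
  emin <- config$convergence$ess_min
  structure(list(parameters = pars,
                 pass = all(pars$rhat <= rmax) && all(pars$ess >= emin),
                 rhat_max = rmax, ess_min = emin),
            class = c("convergence_report", "list"))
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence:", if (x$pass) "PASS" else "FAIL",
      sprintf("(max R-hat %.4f vs %.2f; min ESS %.0f vs %.0f)\n",
              max(x$parameters$rhat), x$rhat_max,
              min(x$parameters$ess), x$ess_min))
  invisible(x)
}
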