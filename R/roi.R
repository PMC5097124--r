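#' Anti-poaching cost parameters
#'
#' The spending benchmark that stabilises large (> 1,000 animal) elephant
#' populations: $215 km^-2 in 1981 USD, inflated to $565 km^-2 in 2016 USD.
#' Current spending at a PA, when unknown, is implied from its population
#' growth rate through a one-parameter log-spend response anchored at the
#' benchmark: `growth(s) = slope_b * (log(s) - log(benchmark_2016))`, so
#' zero growth corresponds exactly to benchmark spending.
#'
#' @param benchmark_1981_usd_km2 zero-decline spending benchmark, USD 1981.
#' @param inflation_factor 1981 to 2016 USD inflation factor (configured
#'   scalar, default `565/215`).
#' @param slope_b growth-rate change per unit log-spend (> 0).
#' @param large_pop_threshold minimum elephant population for the cost
#'   assessment (default 1,000, the range of validity of the benchmark).
#' @return list of class `"cost_params"` including the derived
#'   `benchmark_2016_usd_km2`.
#' @export
cost_params <- function(benchmark_1981_usd_km2 = 215,
                        inflation_factor = 565 / 215,
                        slope_b = 0.05,
                        large_pop_threshold = 1000) {
  if (slope_b <= 0) stop("slope_b must be > 0", call. = FALSE)
  structure(list(
    benchmark_1981_usd_km2 = benchmark_1981_usd_km2,
    inflation_factor = inflation_factor,
    benchmark_2016_usd_km2 = inflate_benchmark(benchmark_1981_usd_km2,
                                               inflation_factor),
    slope_b = slope_b,
    large_pop_threshold = large_pop_threshold),
    class = c("cost_params", "list"))
}

#' Inflate a monetary benchmark by a configured factor
#'
#' @param amount_usd positive amount.
#' @param factor positive inflation factor.
#' @return `amount_usd * factor`.
#' @examples
#' inflate_benchmark(215, 565 / 215)  # 565
#' @export
inflate_benchmark <- function(amount_usd, factor) {
  if (any(amount_usd <= 0) || any(factor <= 0))
    stop("amount and factor must be > 0", call. = FALSE)
  amount_usd * factor
}

#' Implied current conservation spending from a population growth rate
#'
#' Inverts the configured growth model: `spend = benchmark_2016 *
#' exp(growth_rate / slope_b)`.  Zero growth maps exactly to the benchmark;
#' declining populations map to spending below it.
#'
#' @param growth_rate annual proportional population growth (negative for
#'   declines), vectorised.
#' @param params a [cost_params()] list.
#' @return Implied spending, USD 2016 km^-2.
#' @examples
#' spend_from_growth(0)  # 565
#' @export
spend_from_growth <- function(growth_rate, params = cost_params()) {
  params$benchmark_2016_usd_km2 * exp(growth_rate / params$slope_b)
}

# forward model, used for round-trip checks
growth_from_spend <- function(spend, params = cost_params()) {
  params$slope_b * (log(spend) - log(params$benchmark_2016_usd_km2))
}

#' Annual spending shortfall to stabilise one large elephant population
#'
#' `max(0, benchmark_2016 - current_spend) * area_km2`, where current
#' spending is the record's `current_spend_km2` when known and otherwise is
#' implied from its poaching decline rate via
#' `spend_from_growth(-poach_decline_rate)`.
#'
#' @param record a single PA row.
#' @param params a [cost_params()] list.
#' @return Annual USD shortfall, or `NA` (with a message) when the PA's
#'   population does not exceed `large_pop_threshold` -- a skip, not an
#'   error.
#' @export
spending_shortfall <- function(record, params = cost_params()) {
  if (nrow(record) != 1) stop("record must be a single row", call. = FALSE)
  pop <- record$elephant_pop_mean
  if (is.na(pop) || pop <= params$large_pop_threshold) {
    message("PA '", record$pa_id, "' skipped: population ",
            if (is.na(pop)) "unknown" else round(pop),
            " not above ", params$large_pop_threshold)
    return(NA_real_)
  }
  current <- if (!is.na(record$current_spend_km2)) record$current_spend_km2
             else spend_from_growth(-record$poach_decline_rate, params)
  max(0, params$benchmark_2016_usd_km2 - current) * record$area_km2
}

#' Rate of return on anti-poaching investment
#'
#' `100 * (benefit - cost) / cost`.
#'
#' @param total_benefit nonnegative benefit (lost tourism spending averted).
#' @param total_cost positive cost (spending shortfall).
#' @return Percent return.
#' @examples
#' rate_of_return(0.008, 16.9)  # about -100
#' @export
rate_of_return <- function(total_benefit, total_cost) {
  if (any(total_cost <= 0)) stop("total_cost must be > 0", call. = FALSE)
  100 * (total_benefit - total_cost) / total_cost
}

#' Cost and return-on-investment assessment for large elephant populations
#'
#' Restricts to PAs whose population exceeds the threshold, computes each
#' PA's implied current spending and annual shortfall, and compares regional
#' total costs with the regional mean total tourism benefits lost at the same
#' PAs (from a [simulate_valuation()] summary).
#'
#' @param records validated PA table.
#' @param params a [cost_params()] list.
#' @param valuation a `"valuation_summary"`; its `per_pa` means supply the
#'   benefits.  May be `NULL` to get costs only.
#' @return list of class `"cost_assessment"`: `per_pa` (data frame `pa_id`,
#'   `region`, `population`, `implied_current_spend_km2`, `shortfall_usd`),
#'   `by_region` (`region`, `total_cost_usd`, `total_benefit_usd`,
#'   `rate_of_return_percent`) and `threshold`.
#' @export
cost_assessment <- function(records, params = cost_params(),
                            valuation = NULL) {
  records <- validate_pa_table(records)
  keep <- !is.na(records$elephant_pop_mean) &
    records$elephant_pop_mean > params$large_pop_threshold
  r <- records[keep, , drop = FALSE]
  if (!nrow(r))
    stop("no PA exceeds the population threshold of ",
         params$large_pop_threshold, call. = FALSE)
  current <- ifelse(!is.na(r$current_spend_km2), r$current_spend_km2,
                    spend_from_growth(-r$poach_decline_rate, params))
  shortfall <- pmax(0, params$benchmark_2016_usd_km2 - current) * r$area_km2
  per_pa <- data.frame(pa_id = r$pa_id, region = r$region,
                       population = r$elephant_pop_mean,
                       implied_current_spend_km2 = current,
                       shortfall_usd = shortfall,
                       stringsAsFactors = FALSE)
  cost <- vapply(pa_regions, function(rg)
    sum(shortfall[r$region == rg]), 0)
  benefit <- rep(NA_real_, length(pa_regions))
  names(benefit) <- pa_regions
  if (!is.null(valuation)) {
    vp <- valuation$per_pa
    vp <- vp[vp$pa_id %in% r$pa_id, , drop = FALSE]
    benefit <- vapply(pa_regions, function(rg)
      sum(vp$total.mean[vp$region == rg]), 0)
  }
  roi <- ifelse(cost > 0, 100 * (benefit - cost) / cost, NA_real_)
  structure(list(per_pa = per_pa,
                 by_region = data.frame(
                   region = pa_regions, total_cost_usd = cost,
                   total_benefit_usd = benefit,
                   rate_of_return_percent = roi,
                   row.names = NULL, stringsAsFactors = FALSE),
                 threshold = params$large_pop_threshold),
            class = c("cost_assessment", "list"))
}
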