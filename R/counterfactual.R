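#' Elephant density after one year of poaching
#'
#' @param density baseline density, km^-2 (>= 0, vectorised).
#' @param decline_rate annual proportional loss to illegal killing, in
#'   \[0, 1).
#' @return `density * (1 - decline_rate)`.
#' @export
poached_density <- function(density, decline_rate) {
  if (any(is.na(decline_rate)) || any(decline_rate < 0) ||
      any(decline_rate >= 1))
    stop("decline_rate must be in [0, 1)", call. = FALSE)
  if (any(density < 0)) stop("density must be >= 0", call. = FALSE)
  density * (1 - decline_rate)
}

#' Annual visit loss at one PA from poaching-reduced elephant density
#'
#' Predicts median annual visits at the PA's censused density and at the
#' density reduced by its poaching decline rate, holding all other covariates
#' at their fitting-sample means (the PA's own forest status drives the
#' density-by-forest interaction).  The loss is the difference of the two
#' posterior-predictive medians, floored at zero (a negative difference,
#' possible when the posterior density effect for the PA's habitat is
#' negative, is reported as zero with a message).
#'
#' @param fit a `"visitation_fit"`.
#' @param record a single PA row with a population estimate and
#'   `poach_decline_rate`.
#' @return One-row data frame: `pa_id`, `region`, `forest`,
#'   `baseline_density`, `reduced_density`, `median_visits_baseline`,
#'   `median_visits_reduced`, `visit_loss`.
#' @export
visit_loss <- function(fit, record) {
  if (nrow(record) != 1) stop("record must be a single row", call. = FALSE)
  id <- record$pa_id
  if (is.na(record$elephant_pop_mean))
    stop("PA '", id, "' has no elephant population estimate", call. = FALSE)
  if (is.na(record$poach_decline_rate))
    stop("PA '", id, "' has no poaching decline rate", call. = FALSE)
  d0 <- record$elephant_pop_mean / record$censused_area_km2
  d1 <- poached_density(d0, record$poach_decline_rate)
  v0 <- predict_visits(fit, d0, forest = record$forest)$median
  v1 <- predict_visits(fit, d1, forest = record$forest)$median
  loss <- v0 - v1
  if (loss < 0) {
    message("PA '", id, "': negative predicted visit loss (",
            format(loss, digits = 3), ") floored at 0")
    loss <- 0
  }
  data.frame(pa_id = id, region = record$region, forest = record$forest,
             baseline_density = d0, reduced_density = d1,
             median_visits_baseline = v0, median_visits_reduced = v1,
             visit_loss = loss, stringsAsFactors = FALSE)
}

#' Poaching counterfactual across all elephant PAs
#'
#' Applies [visit_loss()] to every record with an elephant population
#' estimate (whether or not the PA has observed visits -- predictions come
#' from the model).
#'
#' @param fit a `"visitation_fit"`.
#' @param records validated PA table.
#' @return data frame of per-PA counterfactual results.
#' @export
counterfactual_table <- function(fit, records) {
  records <- validate_pa_table(records)
  idx <- which(!is.na(records$elephant_pop_mean) &
                 records$elephant_pop_mean > 0)
  if (!length(idx)) stop("no PA records with elephants", call. = FALSE)
  do.call(rbind, lapply(idx, function(i) visit_loss(fit, records[i, ])))
}

#' Aggregate visit losses by region
#'
#' @param results data frame of counterfactual results (needs `region` and
#'   `visit_loss`).
#' @return list with `by_region` (named vector over central/east/south/west,
#'   zero where a region is empty) and `total` (the exact sum of the
#'   regional totals).
#' @export
aggregate_visit_losses <- function(results) {
  if (!nrow(results)) stop("no counterfactual results", call. = FALSE)
  bad <- setdiff(unique(results$region), pa_regions)
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  by_region <- vapply(pa_regions, function(rg)
    sum(results$visit_loss[results$region == rg]), 0)
  list(by_region = by_region, total = sum(by_region))
}
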