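#' @name pa_table
#' @title Protected-area table schema
#' @description
#' All tabular interfaces in the package use one flat comma-separated schema,
#' one row per protected area (PA):
#'
#' * `pa_id`, `name`, `country` — identifiers.
#' * `region` — one of `central`, `east`, `south`, `west`.
#' * `iucn_category` — IUCN management category `II`–`VI`.  Category `I`
#'   rows (tourism largely prohibited) are dropped at read time.
#' * `area_km2` — PA size, km^2 (> 0).
#' * `visits` — average annual tourist visits; empty when unknown.
#' * `elephant_pop_mean` — most recent censused elephant population estimate
#'   (0 for PAs without elephants; empty when unsurveyed).
#' * `elephant_pop_sd` — standard deviation of the population estimate, when
#'   reported in sd form.
#' * `elephant_pop_lo`, `elephant_pop_hi` — population range, when uncertainty
#'   was reported as a range (interpreted as a 95% interval; see
#'   [range_to_normal()]).  Exactly one of \{sd, range, neither\} per row.
#' * `censused_area_km2` — area over which the population was censused;
#'   elephant density is `elephant_pop_mean / censused_area_km2`.
#' * `forest` — `TRUE` if dominant land cover is forest.
#' * `lion` — `TRUE` if lions are present.
#' * `natural_attractiveness` — subjective 1–5 wildlife-viewing score.
#' * `nearby_population` — people living around the PA (> 0).
#' * `accessibility_minutes` — travel time from the nearest large city (> 0).
#' * `country_ppp` — national income, 2006 PPP (> 0).
#' * `poach_decline_rate` — current annual proportional elephant loss to
#'   illegal killing, in \[0, 1); derived upstream from PIKE carcass ratios.
#' * `current_spend_km2` — known conservation spending (USD 2016 km^-2),
#'   empty when unknown.
NULL

pa_regions <- c("central", "east", "south", "west")
pa_iucn_ok <- c("II", "III", "IV", "V", "VI")

pa_numeric_cols <- c("area_km2", "visits", "elephant_pop_mean",
                     "elephant_pop_sd", "elephant_pop_lo", "elephant_pop_hi",
                     "censused_area_km2", "natural_attractiveness",
                     "nearby_population", "accessibility_minutes",
                     "country_ppp", "poach_decline_rate", "current_spend_km2")
pa_logical_cols <- c("forest", "lion")
pa_character_cols <- c("pa_id", "name", "country", "region", "iucn_category")
pa_all_cols <- c(pa_character_cols, "area_km2", "visits", "elephant_pop_mean",
                 "elephant_pop_sd", "elephant_pop_lo", "elephant_pop_hi",
                 "censused_area_km2", pa_logical_cols,
                 "natural_attractiveness", "nearby_population",
                 "accessibility_minutes", "country_ppp", "poach_decline_rate",
                 "current_spend_km2")

#' Uncertainty form of each population estimate
#'
#' @param records a PA table (see [pa_table]).
#' @return Character vector per row: `"sd"`, `"range"`, `"none"` (population
#'   present, no uncertainty reported) or `"zero"` (no elephants / no
#'   population estimate).
#' @export
pa_uncertainty_form <- function(records) {
  has_pop <- !is.na(records$elephant_pop_mean) & records$elephant_pop_mean > 0
  has_sd <- !is.na(records$elephant_pop_sd)
  has_rng <- !is.na(records$elephant_pop_lo) & !is.na(records$elephant_pop_hi)
  form <- ifelse(!has_pop, "zero",
          ifelse(has_sd, "sd", ifelse(has_rng, "range", "none")))
  form
}

#' Validate a PA table
#'
#' Checks the row-level invariants of the schema (see [pa_table]); the first
#' violating row is reported by `pa_id` and field.
#'
#' @param records data frame in the PA schema.
#' @return The validated data frame, invisibly coerced to canonical column
#'   types and order.
#' @export
validate_pa_table <- function(records) {
  miss <- setdiff(pa_all_cols, names(records))
  if (length(miss))
    stop("PA table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  records <- records[, pa_all_cols]
  for (cc in pa_numeric_cols) records[[cc]] <- as.numeric(records[[cc]])
  for (cc in pa_logical_cols) records[[cc]] <- as.logical(records[[cc]])
  for (cc in pa_character_cols) records[[cc]] <- as.character(records[[cc]])

  fail <- function(id, field, why)
    stop(sprintf("invalid PA record '%s', field '%s': %s", id, field, why),
         call. = FALSE)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    id <- r$pa_id
    if (is.na(id) || !nzchar(id)) fail(paste0("row ", i), "pa_id", "missing")
    if (!r$region %in% pa_regions)
      fail(id, "region", paste0("'", r$region, "' not one of ",
                                paste(pa_regions, collapse = "/")))
    if (!r$iucn_category %in% pa_iucn_ok)
      fail(id, "iucn_category",
           paste0("'", r$iucn_category, "' not in II-VI"))
    if (is.na(r$area_km2) || r$area_km2 <= 0)
      fail(id, "area_km2", "must be > 0")
    if (!is.na(r$visits) && r$visits < 0) fail(id, "visits", "must be >= 0")
    has_sd <- !is.na(r$elephant_pop_sd)
    has_lo <- !is.na(r$elephant_pop_lo)
    has_hi <- !is.na(r$elephant_pop_hi)
    if (has_sd && (has_lo || has_hi))
      fail(id, "elephant_pop_sd",
           "sd-form and range-form uncertainty are mutually exclusive")
    if (xor(has_lo, has_hi))
      fail(id, "elephant_pop_lo", "range requires both lo and hi")
    if (has_lo && has_hi && r$elephant_pop_lo > r$elephant_pop_hi)
      fail(id, "elephant_pop_lo", "lo must be <= hi")
    if (has_sd && r$elephant_pop_sd < 0)
      fail(id, "elephant_pop_sd", "must be >= 0")
    if (!is.na(r$elephant_pop_mean)) {
      if (r$elephant_pop_mean < 0) fail(id, "elephant_pop_mean", "must be >= 0")
      if (is.na(r$censused_area_km2) || r$censused_area_km2 <= 0)
        fail(id, "censused_area_km2",
             "must be > 0 when a population estimate is present")
    }
    if (!is.na(r$poach_decline_rate) &&
        (r$poach_decline_rate < 0 || r$poach_decline_rate >= 1))
      fail(id, "poach_decline_rate", "must be in [0, 1)")
    if (!is.na(r$current_spend_km2) && r$current_spend_km2 < 0)
      fail(id, "current_spend_km2", "must be >= 0")
    for (cc in c("natural_attractiveness", "nearby_population",
                 "accessibility_minutes", "country_ppp")) {
      if (is.na(r[[cc]]) || r[[cc]] <= 0) fail(id, cc, "must be > 0")
    }
  }
  if (anyDuplicated(records$pa_id))
    stop("duplicated pa_id: ",
         records$pa_id[duplicated(records$pa_id)][1], call. = FALSE)
  rownames(records) <- NULL
  records
}

#' Read a PA table from CSV
#'
#' Reads, type-coerces and validates a comma-separated PA table (empty cells
#' are missing values).  Rows with IUCN category `I`/`Ia`/`Ib` are dropped
#' with a message, matching the study filter of PAs where tourism is largely
#' prohibited.
#'
#' @param path path to the CSV file.
#' @return Validated data frame of PA records.
#' @export
read_pa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse PA table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!"iucn_category" %in% names(df))
    stop("PA table is missing columns: iucn_category", call. = FALSE)
  cat1 <- df$iucn_category %in% c("I", "Ia", "Ib")
  if (any(cat1)) {
    message("dropped ", sum(cat1), " category I PA record(s)")
    df <- df[!cat1, , drop = FALSE]
  }
  validate_pa_table(df)
}

#' Write a PA table to CSV
#'
#' Numeric fields are serialised at full double precision so that
#' `read_pa_table(write_pa_table(x))` round-trips bit-for-bit.
#'
#' @param records validated PA table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pa_table <- function(records, path) {
  records <- validate_pa_table(records)
  out <- records
  for (cc in pa_numeric_cols) {
    v <- formatC(out[[cc]], digits = 17, format = "g")
    v[is.na(out[[cc]])] <- NA
    out[[cc]] <- v
  }
  for (cc in pa_logical_cols) out[[cc]] <- ifelse(out[[cc]], "TRUE", "FALSE")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write PA table to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read direct-spend and multiplier estimate tables
#'
#' Each file is a one-column CSV (plus an optional `source` label column):
#' `direct_spend_usd` holds per-visit in-country expenditure estimates
#' (USD 2016, > 0); `multiplier` holds total-impact tourism multipliers
#' (>= 1; a total-impact multiplier below one would imply negative indirect
#' spending and is rejected).
#'
#' @param path_direct CSV of direct spend estimates.
#' @param path_mult CSV of multiplier estimates.
#' @return A list of class `"spend_estimates"` with elements
#'   `direct_spend_usd` and `multipliers`.
#' @export
read_spend_estimates <- function(path_direct, path_mult) {
  read_one <- function(path, col) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
    if (!col %in% names(df))
      stop("'", path, "' has no column '", col, "'", call. = FALSE)
    v <- as.numeric(df[[col]])
    if (anyNA(v)) stop("missing/non-numeric value in '", path, "'",
                       call. = FALSE)
    v
  }
  direct <- read_one(path_direct, "direct_spend_usd")
  mult <- read_one(path_mult, "multiplier")
  spend_estimates(direct, mult)
}

#' Construct a validated spend-estimate set
#'
#' @param direct_spend_usd numeric vector of per-visit expenditures (> 0).
#' @param multipliers numeric vector of total-impact multipliers (>= 1).
#' @return A list of class `"spend_estimates"`.
#' @export
spend_estimates <- function(direct_spend_usd, multipliers) {
  if (any(direct_spend_usd <= 0))
    stop("direct spend estimates must be > 0", call. = FALSE)
  if (any(multipliers < 1))
    stop("tourism multipliers must be >= 1", call. = FALSE)
  message(length(direct_spend_usd), " direct-spend and ",
          length(multipliers), " multiplier estimate(s)")
  structure(list(direct_spend_usd = as.numeric(direct_spend_usd),
                 multipliers = as.numeric(multipliers)),
            class = c("spend_estimates", "list"))
}
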