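# Call-measurement table I/O, validation, per-individual aggregation, and
# locality-based spatial thinning of records.

call_record_cols <- c(
  "species", "individual_id", "latitude", "longitude", "date",
  "duration_s", "peak_freq_hz", "n_calls_measured"
)
per_call_cols <- c("species", "individual_id", "call_index", "duration_s", "peak_freq_hz")
profile_cols <- c("species", "range_km2", "max_svl_mm", "season_type", "season_anchor_doy")

#' Read a call-measurement table
#'
#' Reads and validates a CSV of call measurements in one of two schemas:
#' `per_individual` (one row per recorded individual, with location, date
#' and the mean call duration and peak frequency over the calls analysed
#' for that individual) or `per_call` (one row per call, to be aggregated
#' with [aggregate_individuals()]). Dates must be ISO-8601 (`YYYY-MM-DD`).
#' Every row is validated against the field invariants: coordinates within
#' bounds, durations and frequencies finite and positive. Malformed rows
#' are reported with their line numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema `"per_individual"` or `"per_call"`.
#' @return A tibble with the schema's columns, row order preserved.
#' @seealso [write_call_table()], [read_species_profiles()]
#' @export
read_call_table <- function(path, schema = c("per_individual", "per_call")) {
  schema <- match.arg(schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- if (schema == "per_individual") call_record_cols else per_call_cols
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "missing required column(s): %s", paste(missing, collapse = ", ")
    ), class = "callvar_schema_error")
  }
  if (schema == "per_individual") {
    parse_per_individual(tibble::as_tibble(raw[required]))
  } else {
    parse_per_call(tibble::as_tibble(raw[required]))
  }
}

parse_num <- function(x) suppressWarnings(as.numeric(x))

# Collect row-level problems and abort with line numbers (header = line 1).
report_rows <- function(bad, field, problems) {
  if (any(bad)) {
    c(problems, sprintf("line %d: invalid %s", which(bad) + 1L, field))
  } else {
    problems
  }
}

parse_per_individual <- function(df) {
  problems <- character()
  out <- tibble::tibble(
    species = df$species,
    individual_id = df$individual_id,
    latitude = parse_num(df$latitude),
    longitude = parse_num(df$longitude),
    date = as.Date(df$date, format = "%Y-%m-%d"),
    duration_s = parse_num(df$duration_s),
    peak_freq_hz = parse_num(df$peak_freq_hz),
    n_calls_measured = suppressWarnings(as.integer(df$n_calls_measured))
  )
  problems <- report_rows(!is.finite(out$latitude) | abs(out$latitude) > 90, "latitude", problems)
  problems <- report_rows(!is.finite(out$longitude) | abs(out$longitude) > 180, "longitude", problems)
  problems <- report_rows(is.na(out$date), "date (expected YYYY-MM-DD)", problems)
  problems <- report_rows(!is.finite(out$duration_s) | out$duration_s <= 0, "duration_s", problems)
  problems <- report_rows(!is.finite(out$peak_freq_hz) | out$peak_freq_hz <= 0, "peak_freq_hz", problems)
  problems <- report_rows(is.na(out$n_calls_measured) | out$n_calls_measured < 1, "n_calls_measured", problems)
  if (length(problems) > 0) {
    rlang::abort(
      c("call table failed validation:", stats::setNames(problems, rep("x", length(problems)))),
      class = "callvar_validation_error"
    )
  }
  out
}

parse_per_call <- function(df) {
  problems <- character()
  out <- tibble::tibble(
    species = df$species,
    individual_id = df$individual_id,
    call_index = suppressWarnings(as.integer(df$call_index)),
    duration_s = parse_num(df$duration_s),
    peak_freq_hz = parse_num(df$peak_freq_hz)
  )
  problems <- report_rows(is.na(out$call_index) | out$call_index < 1, "call_index", problems)
  problems <- report_rows(!is.finite(out$duration_s) | out$duration_s <= 0, "duration_s", problems)
  problems <- report_rows(!is.finite(out$peak_freq_hz) | out$peak_freq_hz <= 0, "peak_freq_hz", problems)
  if (length(problems) > 0) {
    rlang::abort(
      c("per-call table failed validation:", stats::setNames(problems, rep("x", length(problems)))),
      class = "callvar_validation_error"
    )
  }
  out
}

#' Write a call or result table as CSV
#'
#' @param data A data frame.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_call_table <- function(data, path) {
  df <- as.data.frame(data)
  if ("date" %in% names(df)) df$date <- format(as.Date(df$date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(data)
}

#' Read a species profile table
#'
#' One row per species: geographic range size (km^2), maximum male
#' snout--vent length (mm), breeding-season type and optional season
#' anchor day-of-year.
#'
#' @param path Path to a CSV with columns `species`, `range_km2`,
#'   `max_svl_mm`, `season_type`, `season_anchor_doy`.
#' @return A validated tibble.
#' @export
read_species_profiles <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(profile_cols, names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "missing required column(s): %s", paste(missing, collapse = ", ")
    ), class = "callvar_schema_error")
  }
  out <- tibble::tibble(
    species = raw$species,
    range_km2 = parse_num(raw$range_km2),
    max_svl_mm = parse_num(raw$max_svl_mm),
    season_type = raw$season_type,
    season_anchor_doy = suppressWarnings(as.integer(raw$season_anchor_doy))
  )
  problems <- character()
  problems <- report_rows(!is.finite(out$range_km2) | out$range_km2 <= 0, "range_km2", problems)
  problems <- report_rows(!is.finite(out$max_svl_mm) | out$max_svl_mm <= 0, "max_svl_mm", problems)
  problems <- report_rows(
    !out$season_type %in% c("within_year", "year_spanning", "year_round"),
    "season_type", problems
  )
  if (length(problems) > 0) {
    rlang::abort(
      c("species profile table failed validation:", stats::setNames(problems, rep("x", length(problems)))),
      class = "callvar_validation_error"
    )
  }
  out
}

#' Aggregate per-call measurements to per-individual records
#'
#' Individual call duration and peak frequency are taken as the arithmetic
#' means over the calls analysed for each individual, since the analysis
#' targets variation among rather than within individuals. Individuals
#' must contribute at least `min_calls` calls (default 3); individuals
#' with more than `max_calls` calls are truncated to their first
#' `max_calls` calls (by `call_index`) with a warning.
#'
#' @param calls Per-call tibble (see [read_call_table()] with
#'   `schema = "per_call"`).
#' @param min_calls Minimum calls per individual (default 3).
#' @param max_calls Maximum calls used per individual (default 10; the
#'   first `max_calls` in `call_index` order).
#' @return A tibble with one row per individual: `species`,
#'   `individual_id`, `duration_s`, `peak_freq_hz`, `n_calls_measured`.
#' @export
aggregate_individuals <- function(calls, min_calls = 3, max_calls = 10) {
  counts <- dplyr::count(calls, .data$species, .data$individual_id)
  short <- counts$individual_id[counts$n < min_calls]
  if (length(short) > 0) {
    rlang::abort(sprintf(
      "individual(s) with fewer than %d calls: %s",
      min_calls, paste(short, collapse = ", ")
    ), class = "callvar_insufficient_calls")
  }
  if (any(counts$n > max_calls)) {
    rlang::warn(sprintf(
      "%d individual(s) have more than %d calls; truncating to the first %d by call_index",
      sum(counts$n > max_calls), max_calls, max_calls
    ))
  }
  calls |>
    dplyr::arrange(.data$species, .data$individual_id, .data$call_index) |>
    dplyr::group_by(.data$species, .data$individual_id) |>
    dplyr::slice_head(n = max_calls) |>
    dplyr::summarise(
      duration_s = mean(.data$duration_s),
      peak_freq_hz = mean(.data$peak_freq_hz),
      n_calls_measured = dplyr::n(),
      .groups = "drop"
    )
}

#' Keep one record per exact coordinate
#'
#' Spatial-thinning rule for species with many submissions: at most one
#' record is retained per exact (latitude, longitude) pair, avoiding
#' repeated recordings of what may be the same individual. The earliest
#' record by date is kept; ties are broken by `individual_id`
#' (lexicographic), making the rule deterministic.
#'
#' @param records Per-individual call-record tibble.
#' @return A tibble with at most one row per coordinate pair; the
#'   operation is idempotent.
#' @seealso [thin_min_distance()]
#' @export
thin_unique_location <- function(records) {
  records |>
    dplyr::arrange(.data$date, .data$individual_id) |>
    dplyr::distinct(.data$latitude, .data$longitude, .keep_all = TRUE)
}

#' Keep records at least a minimum distance apart
#'
#' Greedy spatial thinning: records are scanned in (date, individual_id)
#' order and a record is kept iff its haversine distance to every
#' already-kept record is at least `min_km`. All pairwise distances among
#' kept records are therefore >= `min_km`. The scan order is fixed so the
#' result is reproducible; the operation is idempotent.
#'
#' @param records Per-individual call-record tibble.
#' @param min_km Minimum separation in km (> 0; default 1, i.e. recordings
#'   collected at least 1 km apart).
#' @return The thinned tibble, in scan order.
#' @export
thin_min_distance <- function(records, min_km = 1) {
  if (!is.numeric(min_km) || min_km <= 0) {
    rlang::abort("`min_km` must be a positive number")
  }
  records <- dplyr::arrange(records, .data$date, .data$individual_id)
  n <- nrow(records)
  if (n <= 1) return(records)
  keep <- logical(n)
  keep[1] <- TRUE
  for (i in 2:n) {
    d <- haversine_km(
      records$latitude[i], records$longitude[i],
      records$latitude[keep], records$longitude[keep]
    )
    keep[i] <- all(d >= min_km)
  }
  records[keep, ]
}
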