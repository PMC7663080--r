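# Reading, validation, per-individual aggregation, and spatial thinning.

write_csv_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("a valid per-individual table round-trips with parsed types", {
  path <- write_csv_fixture(data.frame(
    species = "Crinia insignifera", individual_id = "ci_001",
    latitude = -32.1, longitude = 116.2, date = "2018-05-04",
    duration_s = 0.22, peak_freq_hz = 3353, n_calls_measured = 10
  ))
  rec <- read_call_table(path, schema = "per_individual")
  expect_equal(nrow(rec), 1)
  expect_s3_class(rec$date, "Date")
  expect_equal(rec$date, as.Date("2018-05-04"))
  expect_equal(rec$duration_s, 0.22)
  expect_equal(rec$n_calls_measured, 10L)
})

test_that("row-level violations are reported with field and line number", {
  path <- write_csv_fixture(data.frame(
    species = c("a", "a"), individual_id = c("x", "y"),
    latitude = c(95, -33), longitude = c(116, 116),
    date = c("2018-05-04", "2018-05-05"),
    duration_s = c(0.2, 0.2), peak_freq_hz = c(3000, 3000),
    n_calls_measured = c(5, 5)
  ))
  err <- expect_error(read_call_table(path, "per_individual"),
                      class = "callvar_validation_error")
  expect_match(conditionMessage(err), "latitude")
  expect_match(conditionMessage(err), "line 2")

  bad_date <- write_csv_fixture(data.frame(
    species = "a", individual_id = "x", latitude = -33, longitude = 116,
    date = "4-May-18", duration_s = 0.2, peak_freq_hz = 3000,
    n_calls_measured = 5
  ))
  expect_error(read_call_table(bad_date, "per_individual"),
               regexp = "date", class = "callvar_validation_error")
})

test_that("a missing required column is a schema error", {
  path <- write_csv_fixture(data.frame(species = "a", individual_id = "x"))
  expect_error(read_call_table(path, "per_individual"),
               regexp = "latitude", class = "callvar_schema_error")
})

test_that("per-call tables preserve call order within individuals", {
  path <- write_csv_fixture(data.frame(
    species = "a", individual_id = "x", call_index = 1:5,
    duration_s = seq(0.1, 0.5, by = 0.1), peak_freq_hz = 3000
  ))
  calls <- read_call_table(path, "per_call")
  expect_equal(nrow(calls), 5)
  expect_equal(calls$call_index, 1:5)
})

test_that("aggregation takes per-individual means and enforces call limits", {
  calls <- tibble::tibble(
    species = "a", individual_id = "x", call_index = 1:3,
    duration_s = c(0.1, 0.2, 0.3), peak_freq_hz = c(1000, 2000, 3000)
  )
  agg <- aggregate_individuals(calls)
  expect_equal(agg$duration_s, 0.2)
  expect_equal(agg$peak_freq_hz, 2000)
  expect_equal(agg$n_calls_measured, 3L)

  const <- dplyr::mutate(calls, duration_s = 0.2)
  expect_equal(aggregate_individuals(const)$duration_s, 0.2)

  expect_error(aggregate_individuals(calls[1:2, ]),
               class = "callvar_insufficient_calls")

  many <- tibble::tibble(
    species = "a", individual_id = "x", call_index = 1:12,
    duration_s = c(rep(0.2, 10), 9, 9), peak_freq_hz = 3000
  )
  expect_warning(agg12 <- aggregate_individuals(many), "truncating")
  expect_equal(agg12$duration_s, 0.2)  # calls 11-12 excluded
  expect_equal(agg12$n_calls_measured, 10L)
})

test_that("aggregated means lie within the range of their inputs", {
  withr::with_seed(7, {
    for (i in 1:10) {
      k <- sample(3:10, 1)
      calls <- tibble::tibble(
        species = "a", individual_id = "x", call_index = seq_len(k),
        duration_s = runif(k, 0.05, 1), peak_freq_hz = runif(k, 500, 5000)
      )
      agg <- aggregate_individuals(calls)
      expect_gte(agg$duration_s, min(calls$duration_s))
      expect_lte(agg$duration_s, max(calls$duration_s))
      expect_gte(agg$peak_freq_hz, min(calls$peak_freq_hz))
      expect_lte(agg$peak_freq_hz, max(calls$peak_freq_hz))
    }
  })
})

test_that("unique-location thinning keeps the earliest record per coordinate", {
  r <- make_records(3)
  expect_equal(nrow(thin_unique_location(r)), 3)

  dup <- make_records(
    2, lat = c(-33, -33), lon = c(146, 146),
    dates = as.Date(c("2018-06-01", "2018-05-04"))
  )
  kept <- thin_unique_location(dup)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$date, as.Date("2018-05-04"))

  tie <- dup
  tie$date <- as.Date(c("2018-05-04", "2018-05-04"))
  expect_equal(thin_unique_location(tie)$individual_id, "sp_001")

  empty <- make_records(0)
  expect_equal(nrow(thin_unique_location(empty)), 0)
})

test_that("minimum-distance thinning keeps the earlier of close pairs", {
  # ~0.5 km apart: 0.0045 degrees of latitude
  close <- make_records(
    2, lat = c(-33, -33.0045), lon = c(146, 146),
    dates = as.Date(c("2018-05-04", "2018-06-01"))
  )
  d <- geosphere::distHaversine(c(146, -33), c(146, -33.0045), r = 6371008.8) / 1000
  expect_lt(d, 1)
  kept <- thin_min_distance(close, min_km = 1)
  expect_equal(kept$date, as.Date("2018-05-04"))

  far <- close
  far$latitude <- c(-33, -33.018)  # ~2 km
  expect_equal(nrow(thin_min_distance(far, min_km = 1)), 2)

  expect_equal(nrow(thin_min_distance(make_records(1), min_km = 1)), 1)
  expect_error(thin_min_distance(close, min_km = 0))
})

test_that("thinning is idempotent and enforces pairwise separation", {
  r <- make_records(80, lat = NULL, lon = NULL, seed = 11)
  # squeeze the points so close pairs exist
  r$latitude <- -33 + (r$latitude + 33.5) * 0.1
  r$longitude <- 146 + (r$longitude - 146.5) * 0.1

  t1 <- thin_min_distance(r, min_km = 2)
  t2 <- thin_min_distance(t1, min_km = 2)
  expect_identical(t1, t2)
  expect_lt(nrow(t1), nrow(r))
  if (nrow(t1) > 1) {
    dm <- geosphere::distm(cbind(t1$longitude, t1$latitude),
                           fun = geosphere::distHaversine) / 1000
    expect_true(all(dm[upper.tri(dm)] >= 2 * (1 - 1e-9)))
  }

  u1 <- thin_unique_location(r)
  expect_identical(u1, thin_unique_location(u1))
})

test_that("species profile tables validate season fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    species = c("a", "b"), range_km2 = c(16853, 1116599),
    max_svl_mm = c(25, 22), season_type = c("within_year", "year_round"),
    season_anchor_doy = c(121, NA)
  ), path, row.names = FALSE)
  prof <- read_species_profiles(path)
  expect_equal(prof$range_km2, c(16853, 1116599))

  utils::write.csv(data.frame(
    species = "a", range_km2 = -1, max_svl_mm = 25,
    season_type = "sometimes", season_anchor_doy = NA
  ), path, row.names = FALSE)
  expect_error(read_species_profiles(path), class = "callvar_validation_error")
})
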