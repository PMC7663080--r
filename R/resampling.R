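# Bootstrap resampling of call records: the sample-size deviation curve and
# the fixed-N draws that produce the four per-sample parameters (SD of call
# duration, SD of peak frequency, convex-hull area, intra-annual day span).

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

#' Per-species RNG seed from a master seed
#'
#' Derives a deterministic seed for one species' resampling stream from a
#' master seed and the species name (a small polynomial hash of the name's
#' UTF-8 bytes). Each species gets its own stream, so adding or removing a
#' species never perturbs another species' draws.
#'
#' @param master_seed Integer master seed.
#' @param species Species name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
species_seed <- function(master_seed, species) {
  bytes <- utf8ToInt(species)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147480009
  as.integer((abs(master_seed) + h) %% 2147480009 + 1)
}

#' Draw a bootstrap sample of records
#'
#' `n` records drawn uniformly with replacement; reproducible given
#' `seed`.
#'
#' @param records Non-empty per-individual call-record tibble.
#' @param n Sample size (>= 2).
#' @param seed Integer seed.
#' @return A tibble of `n` rows.
#' @export
draw_sample <- function(records, n, seed) {
  if (nrow(records) == 0) rlang::abort("`records` must be non-empty")
  if (!is.numeric(n) || n < 2) rlang::abort("`n` must be at least 2")
  idx <- with_local_seed(seed, sample.int(nrow(records), n, replace = TRUE))
  records[idx, ]
}

#' Four summary parameters of one sample
#'
#' For a sample of individuals of one species: (a) the sample standard
#' deviation of call duration (n-1 denominator), (b) the sample SD of peak
#' frequency, (c) the convex-hull area of the recording locations, and
#' (d) the intra-annual day span within the breeding season.
#'
#' @param sample Call-record tibble for a single species, >= 2 rows.
#' @param clock The species' [season_clock()].
#' @return One-row tibble: `sd_duration_s`, `sd_peak_freq_hz`, `area_km2`,
#'   `span_days`, `n`.
#' @export
sample_stats <- function(sample, clock) {
  if (length(unique(sample$species)) > 1) {
    rlang::abort("`sample` must contain a single species")
  }
  if (nrow(sample) < 2) rlang::abort("`sample` must contain at least 2 records")
  tibble::tibble(
    sd_duration_s = stats::sd(sample$duration_s),
    sd_peak_freq_hz = stats::sd(sample$peak_freq_hz),
    area_km2 = convex_hull_area_km2(sample$latitude, sample$longitude),
    span_days = intra_annual_span_days(sample$date, clock),
    n = nrow(sample)
  )
}

# Column-wise sample SDs of a matrix of bootstrap draws (two-pass).
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(colSums((m - rep(mu, each = n))^2) / (n - 1))
}

#' Sample-size deviation curve
#'
#' How far the variability measured from a sample of N individuals sits
#' from the population's: for each N in `n_min..n_max`, `reps` bootstrap
#' samples of N individuals are drawn with replacement and the deviation
#' of each sample's SD (of call duration, and of peak frequency) from the
#' full data's SD is summarised. The default summary is the mean absolute
#' deviation; `deviation = "rmse"` uses the root-mean-square deviation
#' instead. The curve decreases with N, flattening around N = 20.
#'
#' @param records Call-record tibble for one species, >= 2 rows.
#' @param n_min,n_max Sample-size range (defaults 2 and 48; 48 being the
#'   smallest per-species sample the study design anticipates).
#' @param reps Bootstrap replicates per N (default 1000).
#' @param seed Integer seed.
#' @param deviation `"mad"` (mean absolute deviation, default) or
#'   `"rmse"`.
#' @return Tibble with one row per N: `n`, `reps`,
#'   `deviation_duration`, `deviation_freq`, in ascending `n`.
#' @export
sample_size_curve <- function(records, n_min = 2, n_max = 48, reps = 1000,
                              seed = 1, deviation = c("mad", "rmse")) {
  deviation <- match.arg(deviation)
  if (nrow(records) < 2) rlang::abort("`records` must contain at least 2 individuals")
  sd_dur <- stats::sd(records$duration_s)
  sd_frq <- stats::sd(records$peak_freq_hz)
  summarise_dev <- function(x, ref) {
    if (deviation == "mad") mean(abs(x - ref)) else sqrt(mean((x - ref)^2))
  }
  with_local_seed(seed, {
    purrr::map(n_min:n_max, function(n) {
      idx <- matrix(sample.int(nrow(records), n * reps, replace = TRUE), nrow = n)
      tibble::tibble(
        n = n, reps = reps,
        deviation_duration = summarise_dev(
          col_sds(matrix(records$duration_s[idx], nrow = n)), sd_dur
        ),
        deviation_freq = summarise_dev(
          col_sds(matrix(records$peak_freq_hz[idx], nrow = n)), sd_frq
        )
      )
    }) |>
      purrr::list_rbind()
  })
}

#' Fixed-N bootstrap of the four sample parameters
#'
#' Draws `reps` samples of `n` individuals with replacement and computes
#' the four parameters of [sample_stats()] for each draw. N defaults to
#' 20, the sample size at which measured variability stabilises.
#'
#' @param records Call-record tibble for one species, >= 2 rows.
#' @param clock The species' [season_clock()].
#' @param n Individuals per draw (default 20).
#' @param reps Number of draws (default 1000).
#' @param seed Integer seed.
#' @return Tibble of `reps` rows: `draw_index`, `n`, `sd_duration_s`,
#'   `sd_peak_freq_hz`, `area_km2`, `span_days`.
#' @export
fixed_n_resample <- function(records, clock, n = 20, reps = 1000, seed = 1) {
  if (nrow(records) < 2) rlang::abort("`records` must contain at least 2 individuals")
  rel_day <- relativize_doy(records$date, clock)
  cap <- clock$cap_days
  with_local_seed(seed, {
    idx <- matrix(sample.int(nrow(records), n * reps, replace = TRUE), nrow = n)
    tibble::tibble(
      draw_index = seq_len(reps),
      n = n,
      sd_duration_s = col_sds(matrix(records$duration_s[idx], nrow = n)),
      sd_peak_freq_hz = col_sds(matrix(records$peak_freq_hz[idx], nrow = n)),
      area_km2 = vapply(seq_len(reps), function(j) {
        convex_hull_area_km2(records$latitude[idx[, j]], records$longitude[idx[, j]])
      }, numeric(1)),
      span_days = vapply(seq_len(reps), function(j) {
        min(diff(range(rel_day[idx[, j]])), cap)
      }, numeric(1))
    )
  })
}

#' Run the fixed-N bootstrap for every species
#'
#' Applies [fixed_n_resample()] species by species, each with its own RNG
#' stream derived from the master seed via [species_seed()].
#'
#' @param records Multi-species call-record tibble.
#' @param clocks Named list of [season_clock()] objects (see
#'   [season_clocks_from_profiles()]).
#' @param n,reps Passed to [fixed_n_resample()].
#' @param master_seed Master integer seed.
#' @param min_records Species with fewer records are skipped with a
#'   warning (default 2).
#' @return Tidy tibble: `species`, `draw_index`, `n`, `sd_duration_s`,
#'   `sd_peak_freq_hz`, `area_km2`, `span_days`.
#' @export
resample_study <- function(records, clocks, n = 20, reps = 1000,
                           master_seed = 1, min_records = 2) {
  species <- unique(records$species)
  purrr::map(species, function(sp) {
    recs <- records[records$species == sp, ]
    if (nrow(recs) < min_records) {
      rlang::warn(sprintf("skipping %s: only %d record(s)", sp, nrow(recs)))
      return(NULL)
    }
    fixed_n_resample(recs, clocks[[sp]], n = n, reps = reps,
                     seed = species_seed(master_seed, sp)) |>
      dplyr::mutate(species = sp, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Sample-size deviation curves for every species
#'
#' @inheritParams resample_study
#' @param n_min,n_max,reps,deviation Passed to [sample_size_curve()].
#' @return Tidy tibble: `species`, `n`, `reps`, `deviation_duration`,
#'   `deviation_freq`, with class `callvar_curve` for [autoplot()].
#' @export
curve_study <- function(records, n_min = 2, n_max = 48, reps = 1000,
                        master_seed = 1, deviation = "mad", min_records = 2) {
  species <- unique(records$species)
  out <- purrr::map(species, function(sp) {
    recs <- records[records$species == sp, ]
    if (nrow(recs) < min_records) {
      rlang::warn(sprintf("skipping %s: only %d record(s)", sp, nrow(recs)))
      return(NULL)
    }
    sample_size_curve(recs, n_min = n_min, n_max = n_max, reps = reps,
                      seed = species_seed(master_seed, sp),
                      deviation = deviation) |>
      dplyr::mutate(species = sp, .before = 1)
  }) |>
    purrr::list_rbind()
  class(out) <- c("callvar_curve", class(out))
  out
}
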