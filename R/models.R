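# Model layers on the resampled statistics: intraspecific z-scores,
# per-species linear models, the pooled linear mixed model with a species
# random intercept, and the meta-regression of species slopes on range
# size and body size.

z_response_col <- c(sd_duration = "z_sd_duration", sd_freq = "z_sd_freq")
z_predictor_col <- c(area = "z_area", span = "z_span")
raw_z_map <- c(
  sd_duration_s = "z_sd_duration", sd_peak_freq_hz = "z_sd_freq",
  area_km2 = "z_area", span_days = "z_span"
)

#' Intraspecific z-scores of the resampled parameters
#'
#' Standardises each of the four per-draw parameters to mean 0, SD 1
#' within each species (n-1 SD), so species measured on very different
#' scales can be modelled together. A parameter that is constant within a
#' species cannot be standardised; it is set to all zeros and flagged in
#' the `degenerate` attribute.
#'
#' @param samples Tidy resample tibble from [resample_study()] (columns
#'   `species`, `draw_index`, `sd_duration_s`, `sd_peak_freq_hz`,
#'   `area_km2`, `span_days`), >= 2 draws per species.
#' @return Tibble with `species`, `draw_index`, `z_sd_duration`,
#'   `z_sd_freq`, `z_area`, `z_span`; attribute `degenerate` is a tibble
#'   of (species, variable) pairs that were constant.
#' @export
zscore_within_species <- function(samples) {
  counts <- dplyr::count(samples, .data$species)
  if (any(counts$n < 2)) {
    rlang::abort("each species needs at least 2 draws to standardise")
  }
  degenerate <- tibble::tibble(species = character(), variable = character())
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- samples |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(names(raw_z_map)), zscore,
      .names = "z_{.col}"
    )) |>
    dplyr::ungroup()
  for (raw in names(raw_z_map)) {
    const <- samples |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(const = stats::sd(.data[[raw]]) == 0, .groups = "drop")
    if (any(const$const)) {
      degenerate <- dplyr::bind_rows(degenerate, tibble::tibble(
        species = const$species[const$const], variable = raw
      ))
    }
  }
  out <- out |>
    dplyr::select("species", "draw_index", dplyr::starts_with("z_")) |>
    dplyr::rename_with(~ unname(raw_z_map[sub("^z_", "", .x)]), dplyr::starts_with("z_"))
  attr(out, "degenerate") <- degenerate
  out
}

new_callvar_fit <- function(kind, species, response, predictor, covariate = NA_character_,
                            slope, se, t_stat, p_value, df_resid, n_obs,
                            random_intercept_var = NA_real_, status = "ok",
                            model = NULL) {
  structure(
    list(
      kind = kind, species = species, response = response,
      predictor = predictor, covariate = covariate, slope = slope, se = se,
      t_stat = t_stat, p_value = p_value, df_resid = df_resid, n_obs = n_obs,
      random_intercept_var = random_intercept_var, status = status,
      model = model
    ),
    class = "callvar_fit"
  )
}

#' @export
print.callvar_fit <- function(x, ...) {
  cat(sprintf(
    "<callvar_fit: %s> %s ~ %s%s [%s]\n  slope %.5g (SE %.3g), t = %.3f, df = %d, p = %.4g\n",
    x$kind, x$response, x$predictor,
    if (!is.na(x$covariate)) paste0(" | ", x$covariate) else "",
    x$species, x$slope, x$se, x$t_stat, x$df_resid, x$p_value
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted call-variability model
#'
#' One row holding the slope of interest with its standard error,
#' t-statistic, residual degrees of freedom and p-value.
#'
#' @param x A `callvar_fit`.
#' @param ... Unused.
#' @method tidy callvar_fit
#' @export
tidy.callvar_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, species = x$species, response = x$response,
    predictor = x$predictor, covariate = x$covariate,
    slope = x$slope, se = x$se, t_stat = x$t_stat,
    df_resid = x$df_resid, p_value = x$p_value, n_obs = x$n_obs,
    random_intercept_var = x$random_intercept_var, status = x$status
  )
}

#' Model-level summary of a fitted call-variability model
#'
#' @param x A `callvar_fit`.
#' @param ... Unused.
#' @method glance callvar_fit
#' @export
glance.callvar_fit <- function(x, ...) {
  r2 <- if (!is.null(x$model) && inherits(x$model, "lm")) {
    summary(x$model)$r.squared
  } else {
    NA_real_
  }
  tibble::tibble(
    kind = x$kind, n_obs = x$n_obs, df_resid = x$df_resid,
    r_squared = r2, random_intercept_var = x$random_intercept_var,
    status = x$status
  )
}

#' Per-species linear model on z-scores
#'
#' Ordinary least squares of a z-scored response on a z-scored predictor.
#' Because both variables are standardised, the fitted slope equals the
#' Pearson correlation between them. The two-sided p-value uses the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param z_x Predictor values (z-scored), length >= 3.
#' @param z_y Response values, same length.
#' @param species,response,predictor Labels recorded in the fit.
#' @return A `callvar_fit` (see [tidy.callvar_fit()]).
#' @export
fit_species_lm <- function(z_x, z_y, species = NA_character_,
                           response = NA_character_, predictor = NA_character_) {
  if (length(z_x) != length(z_y) || length(z_x) < 3) {
    rlang::abort("`z_x` and `z_y` must have equal length >= 3")
  }
  if (stats::sd(z_x) == 0) {
    rlang::abort("predictor has zero variance; fit is degenerate",
                 class = "callvar_degenerate_fit")
  }
  fit <- stats::lm(z_y ~ z_x)
  co <- summary(fit)$coefficients
  n <- length(z_x)
  new_callvar_fit(
    kind = "species_lm", species = species, response = response,
    predictor = predictor,
    slope = co["z_x", "Estimate"], se = co["z_x", "Std. Error"],
    t_stat = co["z_x", "t value"], p_value = co["z_x", "Pr(>|t|)"],
    df_resid = n - 2L, n_obs = n, model = fit
  )
}

#' Pooled linear mixed model across species
#'
#' Fits, by REML, a linear mixed model of one z-scored response on one
#' z-scored predictor with a species-level random intercept (fixed
#' intercept + fixed slope), testing the overall cross-species influence
#' of the predictor. The reported t-statistic is slope/SE and the
#' two-sided p-value uses the t distribution with `n_obs - 2` residual
#' degrees of freedom (two fixed-effect parameters), the convention used
#' for tables of this design (6 species x 1,000 draws gives df = 5,998).
#'
#' @param z_samples Output of [zscore_within_species()] covering >= 2
#'   species.
#' @param response `"sd_duration"` or `"sd_freq"`.
#' @param predictor `"area"` or `"span"`.
#' @return A `callvar_fit` with `random_intercept_var` set; if the
#'   response is constant the fit is returned with slope 0 and status
#'   `"degenerate"`.
#' @export
fit_pooled_lmm <- function(z_samples, response = c("sd_duration", "sd_freq"),
                           predictor = c("area", "span")) {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  if (length(unique(z_samples$species)) < 2) {
    rlang::abort("the pooled model needs at least 2 species")
  }
  y <- z_samples[[z_response_col[[response]]]]
  x <- z_samples[[z_predictor_col[[predictor]]]]
  n <- length(y)
  if (stats::sd(y) == 0) {
    return(new_callvar_fit(
      kind = "pooled_lmm", species = "pooled", response = response,
      predictor = predictor, slope = 0, se = NA_real_, t_stat = NA_real_,
      p_value = NA_real_, df_resid = n - 2L, n_obs = n,
      random_intercept_var = 0, status = "degenerate"
    ))
  }
  dat <- data.frame(y = y, x = x, species = z_samples$species)
  fit <- lme4::lmer(y ~ x + (1 | species), data = dat, REML = TRUE)
  slope <- unname(lme4::fixef(fit)["x"])
  se <- unname(sqrt(diag(as.matrix(stats::vcov(fit))))[2])
  t_stat <- slope / se
  df <- n - 2L
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "species"][1]
  new_callvar_fit(
    kind = "pooled_lmm", species = "pooled", response = response,
    predictor = predictor, slope = slope, se = se, t_stat = t_stat,
    p_value = 2 * stats::pt(-abs(t_stat), df = df), df_resid = df, n_obs = n,
    random_intercept_var = ri_var, model = fit
  )
}

#' Meta-regression of species slopes on a species covariate
#'
#' Tests whether the per-species model estimates for one relationship
#' (slopes, equal to correlation coefficients on z-scored data) are
#' associated with the species' range size (km^2) or maximum male SVL
#' (mm). Ordinary least squares with an intercept; covariates enter in
#' raw units.
#'
#' @param species_fits Tidy tibble of per-species fits for a single
#'   (response, predictor) relationship: columns `species`, `slope` (and
#'   optionally `response`, `predictor`, `status`).
#' @param profiles Species profile tibble with the covariate column.
#' @param covariate `"range_km2"` or `"max_svl_mm"`.
#' @return A `callvar_fit` of kind `"meta"`.
#' @export
fit_meta_regression <- function(species_fits, profiles,
                                covariate = c("range_km2", "max_svl_mm")) {
  covariate <- match.arg(covariate)
  if ("status" %in% names(species_fits)) {
    species_fits <- species_fits[species_fits$status == "ok", ]
  }
  dat <- dplyr::left_join(
    species_fits[c("species", "slope")],
    profiles[c("species", covariate)],
    by = "species"
  )
  if (any(is.na(dat[[covariate]]))) {
    rlang::abort(sprintf(
      "missing %s for species: %s", covariate,
      paste(dat$species[is.na(dat[[covariate]])], collapse = ", ")
    ))
  }
  if (stats::sd(dat[[covariate]]) == 0) {
    rlang::abort(sprintf("`%s` is constant across species; meta-regression is degenerate",
                         covariate),
                 class = "callvar_degenerate_fit")
  }
  fit <- stats::lm(stats::reformulate(covariate, "slope"), data = dat)
  co <- summary(fit)$coefficients
  n <- nrow(dat)
  response <- if ("response" %in% names(species_fits)) species_fits$response[1] else NA_character_
  predictor <- if ("predictor" %in% names(species_fits)) species_fits$predictor[1] else NA_character_
  new_callvar_fit(
    kind = "meta", species = "all", response = response, predictor = predictor,
    covariate = covariate,
    slope = co[covariate, "Estimate"], se = co[covariate, "Std. Error"],
    t_stat = co[covariate, "t value"], p_value = co[covariate, "Pr(>|t|)"],
    df_resid = n - 2L, n_obs = n, model = fit
  )
}

relationships <- function() {
  tidyr::expand_grid(
    response = c("sd_duration", "sd_freq"),
    predictor = c("span", "area")
  )
}

#' All per-species linear models
#'
#' Fits the four comparisons (SD of call duration and SD of peak
#' frequency, each against intra-annual day span and hull area) for every
#' species: with six species this is 24 models. A comparison whose
#' response or predictor was constant within a species (flagged by
#' [zscore_within_species()]) is reported with status `"degenerate"`
#' rather than fitted.
#'
#' @param z_samples Output of [zscore_within_species()].
#' @return Tidy tibble, one row per species x comparison.
#' @export
fit_all_species_lms <- function(z_samples) {
  degen <- attr(z_samples, "degenerate")
  degen_key <- if (!is.null(degen) && nrow(degen) > 0) {
    paste(degen$species, unname(raw_z_map[degen$variable]))
  } else {
    character()
  }
  combos <- tidyr::expand_grid(species = unique(z_samples$species), relationships())
  purrr::pmap(combos, function(species, response, predictor) {
    zs <- z_samples[z_samples$species == species, ]
    ycol <- z_response_col[[response]]
    xcol <- z_predictor_col[[predictor]]
    if (paste(species, ycol) %in% degen_key || paste(species, xcol) %in% degen_key) {
      return(tidy(new_callvar_fit(
        kind = "species_lm", species = species, response = response,
        predictor = predictor, slope = NA_real_, se = NA_real_,
        t_stat = NA_real_, p_value = NA_real_, df_resid = nrow(zs) - 2L,
        n_obs = nrow(zs), status = "degenerate"
      )))
    }
    tidy(fit_species_lm(zs[[xcol]], zs[[ycol]], species = species,
                        response = response, predictor = predictor))
  }) |>
    purrr::list_rbind()
}

apply_thinning <- function(records, rule = c("none", "unique_location", "min_distance"),
                           min_km = 1) {
  rule <- match.arg(rule)
  switch(rule,
    none = records,
    unique_location = thin_unique_location(records),
    min_distance = thin_min_distance(records, min_km)
  )
}

#' Run the full variability analysis
#'
#' End-to-end pipeline: optional per-species spatial thinning, fixed-N
#' bootstrap of the four sample parameters, intraspecific z-scoring,
#' per-species linear models for the four comparisons, pooled linear
#' mixed models with a species random intercept, meta-regressions of the
#' species slopes on range size and maximum male SVL, and the
#' sample-size deviation curves. With six species the bundle holds
#' 24 species fits, 4 pooled fits and 8 meta-regressions.
#'
#' @param records Multi-species per-individual call-record tibble.
#' @param profiles Species profile tibble (one row per analysed species).
#' @param n,reps Fixed-N bootstrap settings (defaults 20 and 1000).
#' @param n_min,n_max,curve_reps Sample-size curve settings (defaults 2,
#'   48, 1000).
#' @param master_seed Master seed; every random draw in the bundle derives
#'   from it.
#' @param deviation Curve summary, `"mad"` or `"rmse"`.
#' @param thinning `"none"`, `"unique_location"` or `"min_distance"` —
#'   either one rule for all species or a named character vector/list per
#'   species.
#' @param min_km Minimum separation for `"min_distance"` thinning.
#' @return A `callvar_analysis` list: `records_used`, `samples`,
#'   `z_samples`, `species_fits`, `pooled_fits`, `meta_fits`, `curves`,
#'   `manifest`. Use [tidy()] for one combined fit table.
#' @export
run_full_analysis <- function(records, profiles, n = 20, reps = 1000,
                              n_min = 2, n_max = 48, curve_reps = 1000,
                              master_seed = 1, deviation = "mad",
                              thinning = "none", min_km = 1) {
  if (nrow(records) == 0) rlang::abort("`records` is empty")
  records <- purrr::map(unique(records$species), function(sp) {
    rule <- if (length(thinning) > 1 || !is.null(names(thinning))) {
      if (sp %in% names(thinning)) thinning[[sp]] else "none"
    } else {
      thinning
    }
    apply_thinning(records[records$species == sp, ], rule, min_km)
  }) |>
    purrr::list_rbind()
  clocks <- season_clocks_from_profiles(profiles, records)

  samples <- resample_study(records, clocks, n = n, reps = reps,
                            master_seed = master_seed)
  z_samples <- zscore_within_species(samples)
  species_fits <- fit_all_species_lms(z_samples)
  pooled_fits <- purrr::pmap(relationships(), function(response, predictor) {
    tidy(fit_pooled_lmm(z_samples, response, predictor))
  }) |>
    purrr::list_rbind()
  meta_fits <- tidyr::expand_grid(
    relationships(), covariate = c("range_km2", "max_svl_mm")
  ) |>
    purrr::pmap(function(response, predictor, covariate) {
      fits <- species_fits[species_fits$response == response &
                             species_fits$predictor == predictor, ]
      tidy(fit_meta_regression(fits, profiles, covariate))
    }) |>
    purrr::list_rbind()
  curves <- curve_study(records, n_min = n_min, n_max = n_max,
                        reps = curve_reps, master_seed = master_seed,
                        deviation = deviation)
  structure(
    list(
      records_used = records, samples = samples, z_samples = z_samples,
      species_fits = species_fits, pooled_fits = pooled_fits,
      meta_fits = meta_fits, curves = curves,
      manifest = list(
        package_version = as.character(utils::packageVersion("callvar")),
        master_seed = master_seed, n = n, reps = reps,
        n_min = n_min, n_max = n_max, curve_reps = curve_reps,
        deviation = deviation, thinning = thinning, min_km = min_km,
        n_species = length(unique(records$species)),
        n_records = nrow(records)
      )
    ),
    class = "callvar_analysis"
  )
}

#' @export
print.callvar_analysis <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    paste0(
      "<callvar_analysis> %d species, %d records (seed %d)\n",
      "  %d species fits, %d pooled LMM fits, %d meta-regressions\n",
      "  fixed-N bootstrap: n = %d, reps = %d; curves over n = %d..%d\n"
    ),
    m$n_species, m$n_records, m$master_seed,
    nrow(x$species_fits), nrow(x$pooled_fits), nrow(x$meta_fits),
    m$n, m$reps, m$n_min, m$n_max
  ))
  invisible(x)
}

#' Combined fit table of a full analysis
#'
#' @param x A `callvar_analysis`.
#' @param ... Unused.
#' @return All species, pooled and meta fits in one tibble with a `kind`
#'   column.
#' @method tidy callvar_analysis
#' @export
tidy.callvar_analysis <- function(x, ...) {
  dplyr::bind_rows(x$species_fits, x$pooled_fits, x$meta_fits)
}

#' One-row summary of a full analysis
#'
#' @param x A `callvar_analysis`.
#' @param ... Unused.
#' @method glance callvar_analysis
#' @export
glance.callvar_analysis <- function(x, ...) {
  tibble::tibble(
    n_species = x$manifest$n_species,
    n_records = x$manifest$n_records,
    n_species_fits = nrow(x$species_fits),
    n_pooled_fits = nrow(x$pooled_fits),
    n_meta_fits = nrow(x$meta_fits),
    curve_points = nrow(x$curves),
    master_seed = x$manifest$master_seed
  )
}
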