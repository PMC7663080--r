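# z-scoring, per-species linear models, the pooled mixed model, and the
# meta-regression layer.

make_samples <- function(n_draws = 50, species = "a", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    species = species, draw_index = seq_len(n_draws),
    sd_duration_s = abs(rnorm(n_draws, 0.05, 0.01)),
    sd_peak_freq_hz = abs(rnorm(n_draws, 300, 60)),
    area_km2 = runif(n_draws, 0, 5000),
    span_days = runif(n_draws, 0, 120)
  ))
}

test_that("z-scores have mean 0, SD 1 within species; constants are flagged", {
  s <- make_samples(2)
  s$sd_duration_s <- c(1, 3)
  z <- zscore_within_species(s)
  expect_equal(z$z_sd_duration, c(-1, 1) / sqrt(2), tolerance = 1e-10)

  multi <- dplyr::bind_rows(make_samples(200, "a", 1), make_samples(200, "b", 2))
  zm <- zscore_within_species(multi)
  for (sp in c("a", "b")) {
    sub <- zm[zm$species == sp, ]
    for (col in c("z_sd_duration", "z_sd_freq", "z_area", "z_span")) {
      expect_lt(abs(mean(sub[[col]])), 1e-10)
      expect_equal(stats::sd(sub[[col]]), 1, tolerance = 1e-10)
    }
  }

  const <- make_samples(20)
  const$span_days <- 7
  zc <- zscore_within_species(const)
  expect_equal(zc$z_span, rep(0, 20))
  expect_equal(attr(zc, "degenerate"),
               tibble::tibble(species = "a", variable = "span_days"))

  expect_error(zscore_within_species(make_samples(1)), "at least 2")
})

test_that("on z-scored data the species-LM slope equals Pearson correlation", {
  withr::with_seed(4, {
    x <- rnorm(300)
    y <- 0.4 * x + rnorm(300)
  })
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  fit <- fit_species_lm(zx, zy, species = "a", response = "sd_freq", predictor = "area")
  expect_equal(fit$slope, stats::cor(x, y), tolerance = 1e-10)
  expect_equal(fit$t_stat, fit$slope / fit$se, tolerance = 1e-12)
  expect_equal(fit$df_resid, 298L)

  perfect <- suppressWarnings(fit_species_lm(zx, zx))
  expect_equal(perfect$slope, 1, tolerance = 1e-12)
  expect_lt(perfect$p_value, 1e-100)

  expect_error(fit_species_lm(rep(0, 10), rnorm(10)),
               class = "callvar_degenerate_fit")
  expect_error(fit_species_lm(1:2, 1:2))
})

test_that("under the null the species LM is well calibrated", {
  hits <- withr::with_seed(11, {
    vapply(1:100, function(i) {
      x <- rnorm(1000)
      y <- rnorm(1000)
      f <- fit_species_lm((x - mean(x)) / sd(x), (y - mean(y)) / sd(y))
      abs(f$slope) < 0.1 && f$p_value > 0.01
    }, logical(1))
  })
  expect_gte(sum(hits), 95)
})

test_that("tidy and glance return broom-style rows for fits", {
  f <- fit_species_lm(scale(1:20)[, 1], scale(rnorm(20))[, 1],
                      species = "a", response = "sd_duration", predictor = "span")
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("kind", "species", "response", "predictor", "covariate",
                     "slope", "se", "t_stat", "df_resid", "p_value", "n_obs",
                     "random_intercept_var", "status"))
  gl <- glance(f)
  expect_true(is.finite(gl$r_squared))
})

test_that("the pooled LMM collapses to OLS when species are interchangeable", {
  withr::with_seed(6, {
    x <- rnorm(400)
    y <- 0.3 * x + rnorm(400, 0, 0.5)
  })
  z <- tibble::tibble(
    species = rep(c("a", "b"), each = 400), draw_index = rep(1:400, 2),
    z_sd_duration = rep((y - mean(y)) / sd(y), 2),
    z_sd_freq = rep((y - mean(y)) / sd(y), 2),
    z_area = rep((x - mean(x)) / sd(x), 2),
    z_span = rep((x - mean(x)) / sd(x), 2)
  )
  fit <- suppressMessages(fit_pooled_lmm(z, "sd_freq", "area"))
  ols <- stats::coef(stats::lm(z$z_sd_freq ~ z$z_area))[2]
  expect_equal(fit$slope, unname(ols), tolerance = 1e-6)
  expect_equal(fit$df_resid, 798L)
  expect_equal(fit$p_value, 2 * stats::pt(-abs(fit$t_stat), 798), tolerance = 1e-12)

  const <- dplyr::mutate(z, z_sd_freq = 0)
  cf <- fit_pooled_lmm(const, "sd_freq", "area")
  expect_equal(cf$slope, 0)
  expect_equal(cf$random_intercept_var, 0)
  expect_equal(cf$status, "degenerate")

  expect_error(fit_pooled_lmm(z[z$species == "a", ], "sd_freq", "area"),
               "at least 2 species")
})

test_that("the pooled LMM matches closed-form GLS and recovers known effects", {
  # balanced 2-species data: intercept offsets +/-1, common slope 0.5
  n_per <- 500
  withr::with_seed(12, {
    x <- rnorm(2 * n_per)
    g <- rep(c("a", "b"), each = n_per)
    y <- ifelse(g == "a", 1, -1) + 0.5 * x + rnorm(2 * n_per, 0, 0.1)
  })
  z <- tibble::tibble(
    species = g, draw_index = rep(1:n_per, 2),
    z_sd_duration = y, z_sd_freq = y, z_area = x, z_span = x
  )
  fit <- suppressWarnings(fit_pooled_lmm(z, "sd_freq", "area"))
  expect_equal(fit$slope, 0.5, tolerance = 0.02)
  # species means sit at +1 and -1: the REML between-species variance
  # (n-1 denominator over 2 groups) estimates ~2
  expect_gt(fit$random_intercept_var, 0.5)
  expect_lt(fit$random_intercept_var, 8)

  # GLS with the fitted variance components must reproduce the fixed slope
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  tau2 <- vc$vcov[vc$grp == "species"]
  beta <- gls_fixed_effects(y, x, g, sigma2, tau2)
  expect_equal(fit$slope, beta[2], tolerance = 1e-6)
})

test_that("meta-regression matches the normal-equations oracle", {
  fits <- tibble::tibble(
    species = letters[1:6],
    slope = c(0.1, -0.2, 0.05, 0.3, -0.1, 0.15),
    response = "sd_freq", predictor = "area", status = "ok"
  )
  profiles <- tibble::tibble(
    species = letters[1:6],
    range_km2 = c(16853, 1116599, 311818, 1071422, 276209, 14196),
    max_svl_mm = c(25, 22, 64, 69, 62, 56)
  )
  meta <- fit_meta_regression(fits, profiles, "range_km2")
  X <- cbind(1, profiles$range_km2)
  beta <- solve(t(X) %*% X, t(X) %*% fits$slope)
  expect_equal(meta$slope, beta[2], tolerance = 1e-10)
  expect_equal(meta$df_resid, 4L)
  expect_equal(meta$n_obs, 6L)

  equal <- dplyr::mutate(fits, slope = 0.2)
  expect_equal(suppressWarnings(fit_meta_regression(equal, profiles, "max_svl_mm"))$slope,
               0, tolerance = 1e-12)

  linear <- dplyr::mutate(fits, slope = 0.001 * profiles$max_svl_mm)
  perfect <- suppressWarnings(fit_meta_regression(linear, profiles, "max_svl_mm"))
  expect_equal(suppressWarnings(summary(perfect$model))$r.squared, 1, tolerance = 1e-9)
  expect_lt(perfect$p_value, 1e-8)

  expect_error(fit_meta_regression(fits, profiles[1:3, ], "range_km2"), "missing")
})

test_that("degenerate comparisons are reported, not silently fitted", {
  s <- dplyr::bind_rows(make_samples(30, "a", 1), make_samples(30, "b", 2))
  s$span_days[s$species == "a"] <- 5
  z <- zscore_within_species(s)
  fits <- fit_all_species_lms(z)
  expect_equal(nrow(fits), 8)  # 2 species x 4 comparisons
  degen <- fits[fits$species == "a" & fits$predictor == "span", ]
  expect_true(all(degen$status == "degenerate"))
  expect_true(all(is.na(degen$slope)))
  expect_true(all(fits$status[fits$predictor == "area"] == "ok"))
})

test_that("a small full analysis is complete and seed-deterministic", {
  preset <- default_study_preset(3)
  configs <- purrr::map(preset$configs[1:3], function(cfg) {
    cfg$n_individuals <- 40L
    cfg
  })
  study <- generate_study(configs, preset$profiles[1:3, ])
  run1 <- suppressMessages(run_full_analysis(
    study$records, study$profiles, reps = 60, curve_reps = 20,
    n_max = 10, master_seed = 5
  ))
  expect_equal(nrow(run1$species_fits), 12)  # 3 species x 4 comparisons
  expect_equal(nrow(run1$pooled_fits), 4)
  expect_equal(nrow(run1$meta_fits), 8)
  expect_equal(nrow(run1$curves), 3 * 9)
  expect_true(all(tidy(run1)$p_value >= 0 & tidy(run1)$p_value <= 1, na.rm = TRUE))
  ok <- tidy(run1)[tidy(run1)$status == "ok" & is.finite(tidy(run1)$se), ]
  expect_equal(ok$t_stat, ok$slope / ok$se, tolerance = 1e-12)

  run2 <- suppressMessages(run_full_analysis(
    study$records, study$profiles, reps = 60, curve_reps = 20,
    n_max = 10, master_seed = 5
  ))
  expect_equal(tidy(run1), tidy(run2))
  expect_equal(run1$samples, run2$samples)
})
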