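# Independent oracles used across tests. These deliberately take different
# computational routes from the package implementation.

R_EARTH <- 6371.0088

# Spherical triangle area by l'Huilier's theorem (spherical excess), using
# great-circle side lengths. Points as (lat, lon) degrees.
spherical_triangle_area_km2 <- function(p1, p2, p3) {
  side <- function(a, b) {
    # central angle via the spherical law of cosines on unit sphere
    a <- a * pi / 180
    b <- b * pi / 180
    acos(pmin(1, pmax(-1,
      sin(a[1]) * sin(b[1]) + cos(a[1]) * cos(b[1]) * cos(a[2] - b[2])
    )))
  }
  a <- side(p2, p3)
  b <- side(p1, p3)
  cc <- side(p1, p2)
  s <- (a + b + cc) / 2
  e <- 4 * atan(sqrt(max(0,
    tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - cc) / 2)
  )))
  e * R_EARTH^2
}

# Literal two-pass sample standard deviation.
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (length(x) - 1))
}

# Closed-form GLS slope for a random-intercept model, given the variance
# components: beta = (X' V^-1 X)^-1 X' V^-1 y with V = sigma2 I + tau2 Z Z'.
gls_fixed_effects <- function(y, x, group, sigma2, tau2) {
  X <- cbind(1, x)
  g <- as.factor(group)
  Z <- stats::model.matrix(~ g - 1)
  V <- sigma2 * diag(length(y)) + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# Quick per-individual record table with controllable trait values.
make_records <- function(n, species = "sp", durations = NULL, freqs = NULL,
                         lat = NULL, lon = NULL, dates = NULL, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      species = species,
      individual_id = sprintf("%s_%03d", species, seq_len(n)),
      latitude = if (is.null(lat)) runif(n, -34, -33) else lat,
      longitude = if (is.null(lon)) runif(n, 146, 147) else lon,
      date = if (is.null(dates)) as.Date("2018-09-01") + sample(0:120, n, TRUE) else dates,
      duration_s = if (is.null(durations)) rnorm(n, 0.25, 0.05) else durations,
      peak_freq_hz = if (is.null(freqs)) rnorm(n, 3000, 200) else freqs,
      n_calls_measured = 10L
    )
  })
}

default_clock <- function(species = "sp") {
  season_clock(species, "within_year")
}
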