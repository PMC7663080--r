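# Geographic and temporal sample metrics: great-circle distance, convex-hull
# area of recording locations, and breeding-season-relative day arithmetic.

# IUGG mean Earth radius, km
EARTH_RADIUS_KM <- 6371.0088
KM_PER_DEGREE <- EARTH_RADIUS_KM * pi / 180

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius). All arguments are recycled to a common length.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees WGS84.
#' @return Distance(s) in km, always non-negative and symmetric in the
#'   two points.
#' @examples
#' haversine_km(0, 0, 1, 0)  # one degree of latitude, ~111.2 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon, call = rlang::caller_env()) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180)) {
    rlang::abort(
      "latitude must lie in [-90, 90] and longitude in [-180, 180], both finite",
      call = call
    )
  }
  invisible(NULL)
}

#' Convex-hull area of recording locations
#'
#' Area in km^2 of the convex hull of a set of points. Points are projected
#' with a Lambert azimuthal equal-area projection centred on their centroid,
#' then the planar hull area is computed; an equal-area projection keeps the
#' result well defined, and the distortion is negligible at the within-range
#' extents (hundreds of km) this is used for. Fewer than three distinct,
#' non-collinear points give area 0. The result is invariant to point order
#' and duplication and monotone under addition of points.
#'
#' @param lat,lon Coordinates in decimal degrees WGS84 (equal lengths).
#' @return Hull area in km^2 (a single non-negative number).
#' @examples
#' convex_hull_area_km2(c(0, 0, 1), c(0, 1, 0))
#' @export
convex_hull_area_km2 <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  check_coords(lat, lon)
  if (length(lat) == 0) return(0)
  pts <- unique(cbind(lat, lon))
  if (nrow(pts) < 3) return(0)
  xy <- laea_project(pts[, 1], pts[, 2])
  hull <- grDevices::chull(xy$x, xy$y)
  if (length(hull) < 3) return(0)
  shoelace_area(xy$x[hull], xy$y[hull])
}

# Lambert azimuthal equal-area projection centred at the centroid of the
# input points; returns planar coordinates in km.
laea_project <- function(lat, lon, center = NULL) {
  if (is.null(center)) center <- c(mean(lat), mean(lon))
  p0 <- center[1] * pi / 180
  l0 <- center[2] * pi / 180
  p <- lat * pi / 180
  l <- lon * pi / 180
  denom <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)
  k <- sqrt(2 / denom)
  list(
    x = EARTH_RADIUS_KM * k * cos(p) * sin(l - l0),
    y = EARTH_RADIUS_KM * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0))
  )
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Breeding-season clock for a species
#'
#' Defines the day the breeding season is counted from, so that calendar
#' dates can be converted into season-relative days and the intra-annual
#' span of a sample can be measured. The season type controls the anchor:
#' \describe{
#'   \item{within_year}{season falls inside one calendar year; anchor
#'     defaults to Jan 1 (day 1).}
#'   \item{year_spanning}{season crosses the calendar year boundary (e.g.
#'     austral summer breeders); the anchor is the day-of-year of the
#'     species' earliest observation unless given explicitly.}
#'   \item{year_round}{no seasonal structure; anchor Jan 1 and the span is
#'     capped at 364 days.}
#' }
#'
#' @param species Species name.
#' @param season_type One of `"within_year"`, `"year_spanning"`,
#'   `"year_round"`.
#' @param anchor_doy Day-of-year in 1..366 the season starts on, or `NA` to
#'   use the default for the season type (`dates` must then be supplied for
#'   `year_spanning`).
#' @param dates Optional calendar dates of the species' records, used to
#'   derive the anchor for `year_spanning` seasons (the day-of-year of the
#'   earliest record).
#' @return An object of class `season_clock` with fields `species`,
#'   `season_type`, `anchor_doy`, `cap_days` and `period_days` (365).
#' @export
season_clock <- function(species, season_type = c("within_year", "year_spanning", "year_round"),
                         anchor_doy = NA, dates = NULL) {
  season_type <- match.arg(season_type)
  if (is.na(anchor_doy)) {
    anchor_doy <- switch(season_type,
      within_year = 1L,
      year_round = 1L,
      year_spanning = {
        if (is.null(dates) || length(dates) == 0) {
          rlang::abort("a year-spanning season needs either `anchor_doy` or `dates` to derive it from")
        }
        rel <- day_of_year_365(as.Date(dates))
        # anchor = day-of-year of the earliest observation of the season:
        # the relative day that starts the tightest window containing all
        # observations (largest circular gap ends at the anchor)
        u <- sort(unique(rel))
        if (length(u) == 1) u[1] else {
          gaps <- diff(c(u, u[1] + 365))
          u[(which.max(gaps) %% length(u)) + 1]
        }
      }
    )
  }
  anchor_doy <- as.integer(anchor_doy)
  if (anchor_doy < 1 || anchor_doy > 366) {
    rlang::abort("`anchor_doy` must lie in 1..366")
  }
  structure(
    list(
      species = species, season_type = season_type,
      anchor_doy = min(anchor_doy, 365L), period_days = 365L,
      cap_days = if (season_type == "year_round") 364L else 365L
    ),
    class = "season_clock"
  )
}

#' @export
print.season_clock <- function(x, ...) {
  cat(sprintf(
    "<season_clock> %s: %s, anchor day %d\n",
    x$species, x$season_type, x$anchor_doy
  ))
  invisible(x)
}

# Day-of-year on a fixed 365-day year: Feb 29 maps to 59 (same as Feb 28)
# and later days shift back by one, so relative days are year-stable.
day_of_year_365 <- function(date) {
  lt <- as.POSIXlt(date)
  doy <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  adj <- leap & doy >= 60L
  doy[adj] <- doy[adj] - 1L
  doy
}

#' Season-relative day of a calendar date
#'
#' Converts dates to days since the season anchor, on a fixed 365-day year
#' (Feb 29 counts as day 59). Years collapse: only the position within the
#' season matters.
#'
#' @param date Calendar date(s) (`Date` or coercible).
#' @param clock A [season_clock()].
#' @return Relative day(s) in `[0, 365)`.
#' @export
relativize_doy <- function(date, clock) {
  stopifnot(inherits(clock, "season_clock"))
  (day_of_year_365(as.Date(date)) - clock$anchor_doy) %% 365L
}

#' Intra-annual day span of a sample
#'
#' Number of days between the first and last individuals recorded within a
#' (relativized) breeding season: max minus min of the season-relative days
#' of the records, with years collapsed. A single record gives 0. For
#' year-round breeders the span is capped at 364.
#'
#' @param date Calendar dates of the records (non-empty).
#' @param clock A [season_clock()].
#' @return Span in days, in `[0, 365)`.
#' @export
intra_annual_span_days <- function(date, clock) {
  if (length(date) == 0) {
    rlang::abort("`date` must contain at least one record")
  }
  rel <- relativize_doy(date, clock)
  min(diff(range(rel)), clock$cap_days)
}

#' Build season clocks for every species in a profile table
#'
#' @param profiles Species profile table with columns `species`,
#'   `season_type` and optionally `season_anchor_doy`.
#' @param records Call-record table used to derive anchors for
#'   year-spanning seasons.
#' @return Named list of [season_clock()] objects, one per species.
#' @export
season_clocks_from_profiles <- function(profiles, records = NULL) {
  anchors <- if ("season_anchor_doy" %in% names(profiles)) {
    profiles$season_anchor_doy
  } else {
    rep(NA, nrow(profiles))
  }
  clocks <- purrr::pmap(
    list(profiles$species, profiles$season_type, anchors),
    function(sp, st, a) {
      dates <- if (!is.null(records)) records$date[records$species == sp]
      season_clock(sp, st, anchor_doy = a, dates = dates)
    }
  )
  stats::setNames(clocks, profiles$species)
}
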