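#' Daily mean temperature series for one site and season
#'
#' Container for the daily mean temperatures that drive all thermal-forcing
#' computations. Days are indexed by season-relative day of year (DOY):
#' DOY 1 is 1 January of `year`, and DOY <= 0 indexes days of the preceding
#' autumn/winter (DOY 0 = 31 December of `year - 1`). The index must be
#' contiguous; a missing day is stored as `NA` (an explicit gap), never as
#' an implicit zero.
#'
#' @param site_id Site identifier (coerced to character).
#' @param year Calendar year of the event season.
#' @param doy Integer vector of contiguous DOY values (e.g. `-90:250`).
#' @param tmean Numeric vector of daily mean temperatures in degrees
#'   Celsius, same length as `doy`. `NA` marks a gap; non-missing values
#'   must be finite and within \[-60, 60\] degrees C.
#' @param latitude Site latitude in decimal degrees.
#'
#' @return An object of class `temperature_series`.
#' @export
#' @examples
#' ts <- temperature_series("A", 2015, 1:90, rep(5, 90), latitude = 42)
#' spring_mean_temperature(ts)
temperature_series <- function(site_id, year, doy, tmean, latitude) {
  doy <- as.integer(doy)
  tmean <- as.numeric(tmean)
  if (length(doy) != length(tmean)) {
    stop("`doy` and `tmean` must have the same length", call. = FALSE)
  }
  if (length(doy) == 0L) stop("empty temperature series", call. = FALSE)
  if (!identical(doy, seq(doy[1L], doy[length(doy)]))) {
    stop("`doy` must be a contiguous increasing integer sequence; ",
         "encode missing days as NA in `tmean`", call. = FALSE)
  }
  bad <- !is.na(tmean) & (!is.finite(tmean) | tmean < -60 | tmean > 60)
  if (any(bad)) {
    stop("temperatures must be finite and within [-60, 60] degrees C; ",
         "offending DOY: ", paste(utils::head(doy[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(latitude) || length(latitude) != 1L || !is.finite(latitude)) {
    stop("`latitude` must be a single finite number", call. = FALSE)
  }
  structure(
    list(
      site_id = as.character(site_id),
      year = as.integer(year),
      doy_start = doy[1L],
      doy_end = doy[length(doy)],
      tmean = tmean,
      latitude = as.numeric(latitude)
    ),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf(
    "<temperature_series> site %s, season %d, DOY %d..%d (lat %.2f)\n",
    x$site_id, x$year, x$doy_start, x$doy_end, x$latitude
  ))
  cat(sprintf("  mean %.1f C, %d missing day(s)\n",
              mean(x$tmean, na.rm = TRUE), sum(is.na(x$tmean))))
  invisible(x)
}

#' Extract daily temperatures by DOY
#'
#' @param series A [temperature_series()].
#' @param doy Integer DOY value(s) to look up.
#' @return Numeric vector of temperatures; `NA` for gaps.
#' @export
temp_at <- function(series, doy) {
  stopifnot(inherits(series, "temperature_series"))
  idx <- as.integer(doy) - series$doy_start + 1L
  out <- rep(NA_real_, length(idx))
  ok <- idx >= 1L & idx <= length(series$tmean)
  out[ok] <- series$tmean[idx[ok]]
  out
}

series_key <- function(site_id, year) paste(site_id, year, sep = "::")

# Slice of the temperature vector over [from, to]; errors on out-of-range
# or on gaps when `allow_gaps = FALSE`.
series_window <- function(series, from, to, allow_gaps = FALSE,
                          what = "temperature window") {
  if (from < series$doy_start || to > series$doy_end) {
    stop(sprintf(
      "%s needs DOY %d..%d but series for site %s, season %d covers %d..%d",
      what, from, to, series$site_id, series$year,
      series$doy_start, series$doy_end
    ), call. = FALSE)
  }
  x <- series$tmean[(from - series$doy_start + 1L):(to - series$doy_start + 1L)]
  if (!allow_gaps && anyNA(x)) {
    gaps <- (from:to)[is.na(x)]
    stop(sprintf(
      "missing temperature data for site %s, season %d at DOY %s",
      series$site_id, series$year,
      paste(utils::head(gaps, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Mean spring temperature (1 January to 31 March)
#'
#' Arithmetic mean of the daily mean temperature over DOY 1..90 inclusive.
#' The 90-day window is used in all years; 29 February in leap years is an
#' ordinary day of the sequence. This is the covariate of the linear
#' regression model and the spring correction of the MSB model.
#'
#' @param series A [temperature_series()] covering DOY 1..90 with no gaps.
#' @return Mean temperature in degrees C.
#' @export
spring_mean_temperature <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  mean(series_window(series, 1L, 90L, what = "spring mean temperature"))
}

#' Number of chill days since 1 January
#'
#' Counts days in DOY 1..`upto_doy` whose daily mean temperature is strictly
#' below 0 degrees C. This is the NCD covariate of the Alternating and MSB
#' models, re-evaluated for each candidate day.
#'
#' @param series A [temperature_series()].
#' @param upto_doy Last DOY (inclusive) of the counting window; must be >= 1.
#' @return Integer count of chill days.
#' @export
chill_days <- function(series, upto_doy) {
  stopifnot(inherits(series, "temperature_series"))
  upto_doy <- as.integer(upto_doy)
  if (length(upto_doy) != 1L || is.na(upto_doy) || upto_doy < 1L) {
    stop("`upto_doy` must be a single DOY >= 1", call. = FALSE)
  }
  x <- series_window(series, 1L, upto_doy, what = "chill-day count")
  sum(x < 0)
}

# Cumulative chill-day counts for DOY 1..upto (vectorised form used by the
# Alternating/MSB predictors).
chill_day_curve <- function(series, upto_doy) {
  x <- series_window(series, 1L, as.integer(upto_doy),
                     what = "chill-day curve")
  cumsum(x < 0)
}

#' Day length from latitude and day of year
#'
#' Photoperiod in hours by the CBM day-length model of Forsythe et
#' al. (1995), with daylight coefficient p = 0 (sunrise/sunset when the
#' centre of the sun crosses the horizon). Used by the M1 model to scale
#' the required forcing by day length.
#'
#' @param latitude Latitude in decimal degrees, within \[-66, 66\] (polar
#'   day/night latitudes are out of scope).
#' @param doy Day(s) of year in 1..365 (values outside are wrapped
#'   modulo 365, so a season-relative negative DOY maps onto the previous
#'   autumn's calendar day).
#' @return Day length(s) in hours, in (0, 24).
#' @export
#' @examples
#' photoperiod_hours(40, 172) # close to the summer solstice at 40 N
photoperiod_hours <- function(latitude, doy) {
  if (!is.numeric(latitude) || anyNA(latitude) ||
      any(abs(latitude) > 66)) {
    stop("`latitude` must lie within [-66, 66] degrees ",
         "(polar sites unsupported)", call. = FALSE)
  }
  doy <- ((as.numeric(doy) - 1) %% 365) + 1
  # revolution angle and solar declination (radians), CBM parameterisation
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  decl <- asin(0.39795 * cos(theta))
  lat_r <- latitude * pi / 180
  h <- sin(lat_r) * sin(decl) / (cos(lat_r) * cos(decl))
  h <- pmin(1, pmax(-1, h))
  24 - (24 / pi) * acos(h)
}

#' Derived climate covariates of a temperature series
#'
#' Bundles the covariates consumed by the model predictors: spring mean
#' temperature, the cumulative chill-day curve, and the photoperiod at the
#' series' latitude for each DOY of the series range.
#'
#' @param series A [temperature_series()] covering at least DOY 1..90.
#' @return A list of class `covariate_bundle` with elements `tmean_spring`
#'   (degrees C), `ncd` (integer vector over DOY 1..`doy_end`) and
#'   `photoperiod` (hours, named by DOY over the whole series range).
#' @export
compute_covariates <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  doys <- series$doy_start:series$doy_end
  photo <- photoperiod_hours(series$latitude, doys)
  names(photo) <- doys
  structure(
    list(
      tmean_spring = spring_mean_temperature(series),
      ncd = chill_day_curve(series, series$doy_end),
      photoperiod = photo
    ),
    class = "covariate_bundle"
  )
}

#' Read per-site daily temperature CSV into seasonal series
#'
#' Expects columns `site_id, date, tmean_c` (ISO-8601 dates) plus a site
#' metadata table with `site_id, latitude`. Dates are converted to
#' season-relative DOY for the requested event year: days of `year - 1`
#' from October onwards get DOY <= 0.
#'
#' @param temps_file Path to the temperature CSV.
#' @param sites_file Path to the site metadata CSV (`site_id, latitude`,
#'   optionally `longitude`).
#' @param years Event years to build series for; defaults to all years with
#'   January data.
#' @return Named list of [temperature_series()], keyed `site::year`.
#' @export
read_temperature_csv <- function(temps_file, sites_file, years = NULL) {
  tb <- utils::read.csv(temps_file, stringsAsFactors = FALSE)
  need <- c("site_id", "date", "tmean_c")
  if (!all(need %in% names(tb))) {
    stop("temperature CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  st <- utils::read.csv(sites_file, stringsAsFactors = FALSE)
  if (!all(c("site_id", "latitude") %in% names(st))) {
    stop("site CSV must have columns: site_id, latitude", call. = FALSE)
  }
  tb$date <- as.Date(tb$date)
  if (anyNA(tb$date)) stop("unparseable dates in temperature CSV", call. = FALSE)
  tb$cal_year <- as.integer(format(tb$date, "%Y"))
  if (is.null(years)) {
    years <- sort(unique(tb$cal_year[as.integer(format(tb$date, "%m")) == 1L]))
  }
  out <- list()
  for (site in unique(tb$site_id)) {
    lat <- st$latitude[match(site, st$site_id)]
    if (is.na(lat)) {
      stop("site ", site, " missing from site metadata CSV", call. = FALSE)
    }
    sub <- tb[tb$site_id == site, ]
    for (yr in years) {
      jan1 <- as.Date(sprintf("%d-01-01", yr))
      rel <- as.integer(sub$date - jan1) + 1L
      keep <- rel >= -90L & rel <= 250L
      if (!any(keep & rel >= 1L)) next
      rel_k <- rel[keep]
      tm_k <- sub$tmean_c[keep]
      rng <- seq(min(rel_k), max(rel_k))
      tm <- rep(NA_real_, length(rng))
      tm[match(rel_k, rng)] <- tm_k
      out[[series_key(site, yr)]] <-
        temperature_series(site, yr, rng, tm, lat)
    }
  }
  out
}

#' Bundle temperature series with precomputed covariates
#'
#' Builds the environment lookup used by fitting and prediction: for each
#' series, covariates are computed once and the pair is keyed by
#' `site::year` so events can be matched to their climate.
#'
#' @param series_list List of [temperature_series()].
#' @return Named list of class `pheno_env`; each element has `$series` and
#'   `$covariates`.
#' @export
environment_data <- function(series_list) {
  if (inherits(series_list, "temperature_series")) {
    series_list <- list(series_list)
  }
  out <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "temperature_series"))
    # parameter-free cumulative forcing of the fixed GDD model (t1 = 1,
    # Tbase = 0), cached so repeated objective evaluations reuse it
    cache <- NULL
    if (s$doy_start <= 1L && !anyNA(s$tmean)) {
      tm <- s$tmean[(1L - s$doy_start + 1L):length(s$tmean)]
      gdd0 <- cumsum(pmax(tm, 0))
      names(gdd0) <- 1:s$doy_end
      cache <- list(gdd0 = gdd0)
    }
    list(series = s, covariates = compute_covariates(s),
         forcing_cache = cache)
  })
  names(out) <- vapply(series_list,
                       function(s) series_key(s$site_id, s$year), "")
  structure(out, class = "pheno_env")
}

env_lookup <- function(env, site_id, year) {
  key <- series_key(site_id, year)
  e <- env[[key]]
  if (is.null(e)) {
    stop("no temperature series for site ", site_id, ", season ", year,
         call. = FALSE)
  }
  e
}
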