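# Environmental covariates along tracks: day length, wind components and
# the past-to-future lag table.

#' Astronomical day length
#'
#' Hours of daylight at a latitude and date from the CBM
#' declination/hour-angle model (Forsythe et al.): solar declination
#' \eqn{P = \arcsin(0.39795 \cos\theta)} with
#' \eqn{\theta = 0.2163108 + 2\arctan(0.9671396 \tan(0.00860(J - 186)))},
#' and daylight fraction from the hour angle at which the sun's centre
#' sits `horizon_offset_deg` below the horizon. The default offset 0
#' defines daylight by the sun's centre crossing the horizon, which
#' makes day length exactly antisymmetric across the equator;
#' `horizon_offset_deg = 0.8333` reproduces the common
#' upper-limb-plus-refraction convention. Polar day gives 24 h, polar
#' night 0 h.
#'
#' @param lat Latitude in decimal degrees, in \[-90, 90\].
#' @param date A `Date` (or anything `as.Date` accepts), or a day of year.
#' @param horizon_offset_deg Solar depression angle defining daylight
#'   (degrees below the horizon).
#' @return Day length in hours.
#' @export
day_length <- function(lat, date, horizon_offset_deg = 0) {
  stopifnot(all(lat >= -90 & lat <= 90, na.rm = TRUE))
  if (inherits(date, "Date") || is.character(date)) {
    doy <- as.numeric(format(as.Date(date), "%j"))
  } else {
    doy <- (date - 1) %% 365 + 1
  }
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  P <- asin(0.39795 * cos(theta))
  phi <- lat * pi / 180
  a <- (sin(horizon_offset_deg * pi / 180) + sin(phi) * sin(P)) /
    (cos(phi) * cos(P))
  24 - (24 / pi) * acos(pmin(pmax(a, -1), 1))
}

#' Wind support and crosswind along a heading
#'
#' Decomposes a wind vector (`u` eastward, `v` northward, m/s) into the
#' component along a movement heading (wind support; positive = tailwind)
#' and the signed component perpendicular to it (crosswind). Undefined
#' headings (e.g. zero-length steps) yield `NA` for both components.
#'
#' @param u,v Wind components in m/s.
#' @param heading Movement heading in degrees clockwise from geographic
#'   north.
#' @return A data frame with columns `wind_support` and `crosswind`.
#'   `wind_support^2 + crosswind^2 == u^2 + v^2` holds to machine
#'   precision.
#' @export
wind_decompose <- function(u, v, heading) {
  h <- deg2rad(heading)
  ws <- u * sin(h) + v * cos(h)
  cw <- u * cos(h) - v * sin(h)
  bad <- is.na(heading)
  ws[bad] <- NA_real_; cw[bad] <- NA_real_
  data.frame(wind_support = ws, crosswind = cw)
}

#' Environmental values from 10 days past to 10 days ahead
#'
#' For each point, holds the location fixed and shifts the lookup date by
#' each lag (default -10..+10 days), extracting the raster value on the
#' shifted date. Shifted dates outside the series' range are flagged
#' missing. Lag 0 equals [annotate_points()] exactly.
#'
#' @param points Data frame with columns `lon`, `lat`, `date` and
#'   optionally `individual`, `year`.
#' @param series An [env_series].
#' @param lags Integer vector of day offsets.
#' @return A long data frame with one row per point x lag: `point_id`,
#'   `individual`, `year`, `lon`, `lat`, `date`, `lag`, `variable`,
#'   `value`, `missing`.
#' @export
lag_extract <- function(points, series, lags = -10:10) {
  n <- nrow(points)
  indiv <- if ("individual" %in% names(points)) points$individual else NA_character_
  year <- if ("year" %in% names(points)) points$year else NA_integer_
  base <- data.frame(point_id = seq_len(n), individual = indiv, year = year,
                     lon = points$lon, lat = points$lat,
                     date = as.Date(points$date))
  out <- do.call(rbind, lapply(lags, function(tau) {
    p <- base
    p$lag <- tau
    shifted <- data.frame(lon = p$lon, lat = p$lat, date = p$date + tau)
    p$value <- as.numeric(annotate_points(shifted, series, quiet = TRUE))
    p
  }))
  out$variable <- series$variable
  out$missing <- is.na(out$value)
  rownames(out) <- NULL
  out[order(out$point_id, out$lag),
      c("point_id", "individual", "year", "lon", "lat", "date", "lag",
        "variable", "value", "missing")]
}

#' Multi-variable lag table
#'
#' Runs [lag_extract()] for each raster series and (optionally) appends
#' day length, recomputed for each shifted date at the fixed latitude, as
#' a further variable.
#'
#' @inheritParams lag_extract
#' @param series_map Named list of [env_series] objects.
#' @param include_day_length Append a `day_length` variable (hours)?
#' @return A long data frame in [lag_extract()] format.
#' @export
lag_table <- function(points, series_map, lags = -10:10,
                      include_day_length = TRUE) {
  pieces <- lapply(series_map, function(s) lag_extract(points, s, lags))
  if (include_day_length) {
    dl <- lag_extract_day_length(points, lags)
    pieces <- c(pieces, list(dl))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

lag_extract_day_length <- function(points, lags = -10:10) {
  n <- nrow(points)
  indiv <- if ("individual" %in% names(points)) points$individual else NA_character_
  year <- if ("year" %in% names(points)) points$year else NA_integer_
  base <- data.frame(point_id = seq_len(n), individual = indiv, year = year,
                     lon = points$lon, lat = points$lat,
                     date = as.Date(points$date))
  out <- do.call(rbind, lapply(lags, function(tau) {
    p <- base
    p$lag <- tau
    p$value <- day_length(p$lat, p$date + tau)
    p
  }))
  out$variable <- "day_length"
  out$missing <- is.na(out$value)
  rownames(out) <- NULL
  out[order(out$point_id, out$lag),
      c("point_id", "individual", "year", "lon", "lat", "date", "lag",
        "variable", "value", "missing")]
}
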