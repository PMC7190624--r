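# Daily raster series container: one variable on a regular lon/lat grid,
# one layer per calendar day.

#' Daily environmental raster series
#'
#' Container for a date-indexed stack of regular lon/lat grids holding one
#' environmental variable (binary snow cover, temperature, NDVI, wind
#' components, ...). Values are stored as a 3-d array indexed
#' `[lat, lon, date]`.
#'
#' @param variable Variable name (e.g. `"snow"`).
#' @param dates Vector of consecutive `Date`s (daily, no gaps).
#' @param lat,lon Strictly increasing regular axes of cell-centre
#'   coordinates in decimal degrees.
#' @param values Numeric array with dim `c(length(lat), length(lon),
#'   length(dates))`.
#' @return An object of class `env_series`.
#' @export
env_series <- function(variable, dates, lat, lon, values) {
  dates <- as.Date(dates)
  if (length(dates) == 0) stop("empty date range")
  if (any(diff(as.integer(dates)) != 1))
    stop("dates must be consecutive calendar days with no gaps")
  if (length(lat) < 1 || length(lon) < 1) stop("degenerate grid (0 cells)")
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("lat axis must be strictly increasing")
  if (length(lon) > 1 && any(diff(lon) <= 0)) stop("lon axis must be strictly increasing")
  values <- array(values, dim = c(length(lat), length(lon), length(dates)))
  structure(list(variable = variable, dates = dates, lat = lat, lon = lon,
                 values = values),
            class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("<env_series '%s'>  %d x %d cells, %d days (%s .. %s)\n",
              x$variable, length(x$lat), length(x$lon), length(x$dates),
              format(min(x$dates)), format(max(x$dates))))
  cat(sprintf("  lat %.3f..%.3f  lon %.3f..%.3f  values %.3g..%.3g\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              min(x$values), max(x$values)))
  invisible(x)
}

# Nearest index on a regular increasing axis; exact midpoints resolve to the
# lower index. NA outside the axis range extended by half a cell.
.nearest_index <- function(ax, x) {
  n <- length(ax)
  if (n == 1) {
    j <- rep(1L, length(x))
    j[is.na(x)] <- NA_integer_
    return(j)
  }
  step <- ax[2] - ax[1]
  d <- (x - ax[1]) / step
  i0 <- floor(d)
  frac <- d - i0
  idx <- as.integer(i0 + (frac > 0.5 + 1e-9) + 1L)  # tie -> lower index
  idx <- pmin(pmax(idx, 1L), n)                     # clamp boundary half-cells
  idx[is.na(d) | d < -0.5 - 1e-9 | d > n - 0.5 + 1e-9] <- NA_integer_
  idx
}

# Matrix slice for one date (lat x lon), NULL if outside range.
env_slice <- function(series, date) {
  k <- match(as.Date(date), series$dates)
  if (is.na(k)) return(NULL)
  series$values[, , k, drop = TRUE]
}

#' Annotate point locations with a raster series
#'
#' Looks up the nearest-cell value for each point on the point's own
#' calendar date. Points outside the grid (beyond half a cell from the
#' outermost cell centres) or outside the covered date range get `NA`;
#' the number of such misses is reported via a message and attached as
#' attribute `n_missing`.
#'
#' @param points A data frame with columns `lon`, `lat` and `date`
#'   (coercible to `Date`).
#' @param series An [env_series].
#' @param quiet Suppress the missing-count message.
#' @return Numeric vector of annotated values, one per point, with
#'   attribute `n_missing`.
#' @export
annotate_points <- function(points, series, quiet = FALSE) {
  stopifnot(all(c("lon", "lat", "date") %in% names(points)))
  n <- nrow(points)
  ila <- .nearest_index(series$lat, points$lat)
  ilo <- .nearest_index(series$lon, points$lon)
  ida <- match(as.Date(points$date), series$dates)
  out <- rep(NA_real_, n)
  ok <- !is.na(ila) & !is.na(ilo) & !is.na(ida)
  if (any(ok))
    out[ok] <- series$values[cbind(ila[ok], ilo[ok], ida[ok])]
  nmiss <- sum(!ok)
  if (nmiss > 0 && !quiet)
    message(sprintf("annotate_points: %d of %d points outside grid or date range (NA)",
                    nmiss, n))
  attr(out, "n_missing") <- nmiss
  out
}

#' Write / read a raster series as long-format CSV
#'
#' Plain-text serialisation with columns `date, lat, lon, value`, one row
#' per cell-day. Intended for small grids and interchange with external
#' tools.
#'
#' @param series An [env_series].
#' @param path File path.
#' @export
write_env_series <- function(series, path) {
  grid <- expand.grid(lat = series$lat, lon = series$lon,
                      date = format(series$dates), KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(date = grid$date, lat = grid$lat, lon = grid$lon,
                   value = as.vector(series$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_series
#' @param variable Variable name to assign on read.
#' @export
read_env_series <- function(path, variable = "value") {
  df <- utils::read.csv(path)
  dates <- sort(unique(as.Date(df$date)))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  o <- order(match(as.Date(df$date), dates), match(df$lon, lon),
             match(df$lat, lat))
  env_series(variable, dates, lat, lon, df$value[o])
}
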