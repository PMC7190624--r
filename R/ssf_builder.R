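# Step-selection strata: fit the empirical movement kernel, sample
# alternative endpoints, annotate chosen and alternative locations.

#' Fit the step-length / turn-angle distribution
#'
#' Exponential maximum-likelihood fit to observed step lengths
#' (`rate = 1 / mean(length)`) plus the empirical sample of observed
#' turn angles, resampled with replacement when drawing alternatives.
#'
#' @param steps Step data frame from [step_geometry()] (possibly pooled
#'   across bursts/individuals of one species), or a numeric vector of
#'   step lengths in km.
#' @param turns Optional numeric vector of turn angles (degrees) when
#'   `steps` is a bare length vector.
#' @return A `step_distribution`: list with `rate` (1/km), `mean_km`,
#'   `turns` (degrees), `n`.
#' @export
fit_step_distribution <- function(steps, turns = NULL) {
  if (is.data.frame(steps)) {
    lengths <- steps$length_km
    turns <- steps$turn[!is.na(steps$turn)]
  } else {
    lengths <- as.numeric(steps)
    if (is.null(turns)) turns <- numeric(0)
  }
  lengths <- lengths[is.finite(lengths)]
  if (sum(lengths > 0) < 5)
    stop("need at least 5 steps with positive length")
  m <- mean(lengths)
  if (m <= 0) stop("all step lengths are zero")
  structure(list(rate = 1 / m, mean_km = m, turns = turns,
                 n = length(lengths)),
            class = "step_distribution")
}

#' @export
print.step_distribution <- function(x, ...) {
  cat(sprintf("<step_distribution> exponential rate %.4f /km (mean %.1f km), %d steps, %d turn angles\n",
              x$rate, x$mean_km, x$n, length(x$turns)))
  invisible(x)
}

#' Sample alternative step endpoints
#'
#' Draws `K` alternative endpoints from a step's start fix: distances
#' from the fitted exponential kernel, absolute bearings equal to the
#' previous step's heading plus a turn angle resampled (with
#' replacement) from the empirical sample. Seeded and reproducible.
#'
#' @param lon0,lat0 Start fix coordinates (degrees).
#' @param prev_heading Heading of the previous step (degrees from
#'   north); must be defined.
#' @param dist A `step_distribution` from [fit_step_distribution()].
#' @param K Number of alternatives (>= 1).
#' @param seed Optional integer seed.
#' @return Data frame `lon`, `lat`, `bearing`, `dist_km` with `K` rows.
#' @export
sample_alternatives <- function(lon0, lat0, prev_heading, dist, K = 10,
                                seed = NULL) {
  if (is.na(prev_heading)) stop("previous heading undefined; cannot sample")
  stopifnot(K >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rexp(K, dist$rate)
  turn <- if (length(dist$turns) > 0)
    sample(dist$turns, K, replace = TRUE) else rep(0, K)
  b <- (prev_heading + turn) %% 360
  dest <- destination_point(lon0, lat0, b, d)
  data.frame(lon = dest[, "lon"], lat = dest[, "lat"], bearing = b,
             dist_km = d)
}

#' Build step-selection strata
#'
#' One stratum per chosen step that has a previous heading (the first
#' step of each burst lacks a turn-angle reference and is skipped,
#' counted in attribute `n_skipped_first`): the chosen endpoint plus `K`
#' alternatives sampled by [sample_alternatives()], all sharing the
#' step's start fix and start date. Covariates: snow at each endpoint on
#' the start date and, at the one-day step scale (or when
#' `include_wind = TRUE`), wind support and crosswind along each
#' endpoint's own start-to-endpoint bearing, from the start-date wind
#' field at the endpoint. Alternatives falling off the grid are redrawn
#' up to `max_retry` times, after which the stratum is dropped (counted
#' in attribute `n_dropped_offgrid`).
#'
#' @param bursts List of burst data frames from [resample_steps()].
#' @param series_map Named list of [env_series] with `snow` and
#'   optionally `wind_u`, `wind_v`.
#' @param dist A `step_distribution`; default fitted from the bursts'
#'   own pooled steps.
#' @param K Alternatives per stratum (default 10).
#' @param seed Integer seed.
#' @param include_wind Compute wind covariates? Defaults to `TRUE` only
#'   at the one-day step scale.
#' @param max_retry Redraw cap for off-grid alternatives.
#' @return Long data frame: `stratum`, `individual`, `year`, `date`,
#'   `case` (1 chosen / 0 alternative), `lon0`, `lat0`, `lon`, `lat`,
#'   `bearing`, `dist_km`, `snow` (+ `wind_support`, `crosswind`), with
#'   accounting attributes.
#' @export
build_strata <- function(bursts, series_map, dist = NULL, K = 10,
                         seed = 1L, include_wind = NULL, max_retry = 100L) {
  stopifnot("snow" %in% names(series_map))
  if (length(bursts) == 0) return(NULL)
  step_days <- attr(bursts[[1]], "step_days")
  if (is.null(include_wind))
    include_wind <- !is.null(step_days) && isTRUE(step_days == 1)
  has_wind <- all(c("wind_u", "wind_v") %in% names(series_map))
  if (include_wind && !has_wind)
    stop("include_wind = TRUE but wind_u/wind_v series missing")
  if (is.null(dist)) {
    all_steps <- do.call(rbind, lapply(bursts, step_geometry))
    dist <- fit_step_distribution(all_steps)
  }
  set.seed(seed)
  snow <- series_map$snow
  lon_rng <- range(snow$lon) + c(-0.5, 0.5) * (snow$lon[2] - snow$lon[1])
  lat_rng <- range(snow$lat) + c(-0.5, 0.5) * (snow$lat[2] - snow$lat[1])
  out <- list(); si <- 0L
  n_skipped <- 0L; n_dropped <- 0L
  for (b in bursts) {
    stp <- step_geometry(b)
    for (i in seq_len(nrow(stp))) {
      prev_heading <- if (i > 1) stp$heading[i - 1] else NA_real_
      if (is.na(prev_heading)) { n_skipped <- n_skipped + 1L; next }
      date0 <- as.Date(stp$t0[i])
      # chosen endpoint
      ch <- data.frame(lon = stp$lon1[i], lat = stp$lat1[i],
                       bearing = stp$heading[i], dist_km = stp$length_km[i])
      # alternatives, redrawing any off-grid draw
      alt <- sample_alternatives(stp$lon0[i], stp$lat0[i], prev_heading,
                                 dist, K)
      bad <- which(alt$lon < lon_rng[1] | alt$lon > lon_rng[2] |
                     alt$lat < lat_rng[1] | alt$lat > lat_rng[2])
      tries <- 0L
      while (length(bad) > 0 && tries < max_retry) {
        redraw <- sample_alternatives(stp$lon0[i], stp$lat0[i],
                                      prev_heading, dist, length(bad))
        alt[bad, ] <- redraw
        bad <- which(alt$lon < lon_rng[1] | alt$lon > lon_rng[2] |
                       alt$lat < lat_rng[1] | alt$lat > lat_rng[2])
        tries <- tries + 1L
      }
      if (length(bad) > 0) { n_dropped <- n_dropped + 1L; next }
      ep <- rbind(ch, alt)
      ep$case <- c(1L, rep(0L, K))
      pts <- data.frame(lon = ep$lon, lat = ep$lat, date = date0)
      ep$snow <- as.numeric(annotate_points(pts, snow, quiet = TRUE))
      if (include_wind) {
        wu <- as.numeric(annotate_points(pts, series_map$wind_u, quiet = TRUE))
        wv <- as.numeric(annotate_points(pts, series_map$wind_v, quiet = TRUE))
        wd <- wind_decompose(wu, wv, ep$bearing)
        ep$wind_support <- wd$wind_support
        ep$crosswind <- wd$crosswind
      }
      si <- si + 1L
      ep <- cbind(data.frame(
        stratum = sprintf("%s_%s_b%d_s%d", stp$individual[i], stp$year[i],
                          stp$burst[i], i),
        individual = stp$individual[i], year = stp$year[i], date = date0,
        lon0 = stp$lon0[i], lat0 = stp$lat0[i]), ep)
      out[[si]] <- ep
    }
  }
  res <- if (si > 0) do.call(rbind, out) else NULL
  if (!is.null(res)) rownames(res) <- NULL
  structure(res, n_skipped_first = n_skipped, n_dropped_offgrid = n_dropped,
            K = K, step_days = step_days)
}
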