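# Synthetic study system: a northward-receding snowmelt front, smooth
# temperature/NDVI/wind fields, and agents whose step choice follows a
# stratum-softmax with known selection coefficients.

#' Snowmelt-front configuration
#'
#' Defines the grid, date range and melt dynamics of the synthetic snow
#' series. The melt front latitude is \eqn{L(t) = L_0 + v t} (degrees,
#' day t counted from the first date); each cell's snow probability
#' before thresholding is \eqn{logistic(k (lat - L(t)))}, which makes
#' per-cell melt timing sigmoidal: slow far from the front, fastest when
#' the front passes (50% snow probability), slow again at the end.
#'
#' Defaults describe a low-Arctic spring: a 10x20-degree window, 0.25-degree
#' cells, March through June, a front starting at 57N and receding north
#' at 0.2 degrees/day.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid extent, decimal degrees.
#' @param cell_deg Cell size in degrees (> 0).
#' @param dates Consecutive daily `Date` vector.
#' @param front_lat0 Front latitude on the first date (degrees).
#' @param front_speed Northward front speed in degrees/day (>= 0).
#' @param melt_steepness Logistic slope in latitude (1/degrees).
#' @param noise_p Per-cell daily Bernoulli flip probability, in \[0, 0.5).
#' @param seed Integer seed for the noise field.
#' @return A `snow_front_config` list.
#' @export
snow_front_config <- function(lon_min = 15, lon_max = 25,
                              lat_min = 55, lat_max = 75,
                              cell_deg = 0.25,
                              dates = seq(as.Date("2016-03-01"),
                                          as.Date("2016-06-30"), by = "day"),
                              front_lat0 = 57, front_speed = 0.2,
                              melt_steepness = 2, noise_p = 0,
                              seed = 1L) {
  stopifnot(cell_deg > 0, length(dates) >= 1, front_speed >= 0,
            noise_p >= 0, noise_p < 0.5,
            lon_max > lon_min, lat_max > lat_min)
  structure(list(lon_min = lon_min, lon_max = lon_max, lat_min = lat_min,
                 lat_max = lat_max, cell_deg = cell_deg,
                 dates = as.Date(dates), front_lat0 = front_lat0,
                 front_speed = front_speed, melt_steepness = melt_steepness,
                 noise_p = noise_p, seed = as.integer(seed)),
            class = "snow_front_config")
}

# Cell-centre axes for a config.
.cfg_axes <- function(config) {
  half <- config$cell_deg / 2
  lat <- seq(config$lat_min + half, config$lat_max - half + 1e-12,
             by = config$cell_deg)
  lon <- seq(config$lon_min + half, config$lon_max - half + 1e-12,
             by = config$cell_deg)
  if (length(lat) < 1 || length(lon) < 1) stop("degenerate grid (0 cells)")
  list(lat = lat, lon = lon)
}

#' Front latitude at each date
#'
#' @param config A [snow_front_config()].
#' @param dates Dates at which to evaluate; defaults to the config's.
#' @return Front latitude L(t) in degrees.
#' @export
front_latitude <- function(config, dates = config$dates) {
  t <- as.numeric(as.Date(dates) - config$dates[1])
  config$front_lat0 + config$front_speed * t
}

#' Simulate the binary snow-cover series
#'
#' Deterministic core: cell is snow-covered iff its logistic snow
#' probability exceeds 0.5, i.e. iff its latitude is at or above the
#' front latitude L(t). Because L(t) is non-decreasing, once a cell has
#' melted it stays snow-free (no re-freeze). Optional Bernoulli noise
#' flips cells independently per day, re-introducing observation-like
#' flicker; values are always strictly binary.
#'
#' @param config A [snow_front_config()].
#' @return An [env_series] named `"snow"` with values in \{0, 1\}.
#' @export
make_snow_series <- function(config) {
  ax <- .cfg_axes(config)
  nlat <- length(ax$lat); nlon <- length(ax$lon); nd <- length(config$dates)
  L <- front_latitude(config)
  vals <- array(0, dim = c(nlat, nlon, nd))
  for (k in seq_len(nd)) {
    p <- stats::plogis(config$melt_steepness * (ax$lat - L[k]))
    vals[, , k] <- matrix(as.numeric(p >= 0.5), nlat, nlon)
  }
  if (config$noise_p > 0) {
    set.seed(config$seed)
    flip <- array(stats::runif(nlat * nlon * nd) < config$noise_p,
                  dim = c(nlat, nlon, nd))
    vals <- abs(vals - as.numeric(flip))
  }
  env_series("snow", config$dates, ax$lat, ax$lon, vals)
}

#' Simulate temperature, NDVI and wind fields
#'
#' Temperature and NDVI are affine in day-of-run and latitude (warming
#' and greening as spring progresses, colder and barer to the north) plus
#' optional seeded Gaussian noise; NDVI is clipped to \[-1, 1\]. Wind U/V
#' are a configurable mean vector plus a smooth seeded random field
#' (low-order random-phase harmonics over the grid, redrawn each day).
#'
#' Defaults: warming 0.25 degC/day and -0.8 degC per degree latitude from
#' 5 degC at the grid's south edge on day 0; greening 0.01 NDVI/day and
#' -0.02 NDVI per degree latitude from 0.2; calm mean wind.
#'
#' @param config A [snow_front_config()] (grid/dates/seed are reused).
#' @param temp0,temp_day,temp_lat Temperature intercept (degC at the
#'   south edge, day 0), slope per day, slope per degree latitude north.
#' @param ndvi0,ndvi_day,ndvi_lat Same for NDVI.
#' @param wind_mean Mean wind vector `c(u, v)` in m/s.
#' @param noise_sd Named vector of Gaussian noise SDs for `temp`, `ndvi`,
#'   `wind`.
#' @return Named list of [env_series]: `temp`, `ndvi`, `wind_u`, `wind_v`.
#' @export
make_env_fields <- function(config,
                            temp0 = 5, temp_day = 0.25, temp_lat = 0.8,
                            ndvi0 = 0.2, ndvi_day = 0.01, ndvi_lat = 0.02,
                            wind_mean = c(0, 0),
                            noise_sd = c(temp = 0, ndvi = 0, wind = 2)) {
  ax <- .cfg_axes(config)
  nlat <- length(ax$lat); nlon <- length(ax$lon); nd <- length(config$dates)
  day <- as.numeric(config$dates - config$dates[1])
  dlat <- ax$lat - config$lat_min
  set.seed(config$seed + 1L)
  sd_of <- function(nm) {
    s <- noise_sd[nm]
    if (is.na(s)) 0 else as.numeric(s)
  }

  base_field <- function(b0, bday, blat, s) {
    vals <- array(0, dim = c(nlat, nlon, nd))
    for (k in seq_len(nd)) {
      m <- matrix(b0 + bday * day[k] - blat * dlat, nlat, nlon)
      if (s > 0) m <- m + matrix(stats::rnorm(nlat * nlon, 0, s), nlat, nlon)
      vals[, , k] <- m
    }
    vals
  }
  temp <- base_field(temp0, temp_day, temp_lat, sd_of("temp"))
  ndvi <- base_field(ndvi0, ndvi_day, ndvi_lat, sd_of("ndvi"))
  ndvi <- pmin(1, pmax(-1, ndvi))

  smooth_field <- function(mean_val, s) {
    vals <- array(mean_val, dim = c(nlat, nlon, nd))
    if (s > 0) {
      # 3 random-phase harmonics per day: smooth in space, seeded.
      gx <- (seq_len(nlon) - 1) / max(1, nlon - 1)
      gy <- (seq_len(nlat) - 1) / max(1, nlat - 1)
      for (k in seq_len(nd)) {
        f <- matrix(0, nlat, nlon)
        for (h in 1:3) {
          a <- stats::rnorm(1, 0, s / sqrt(3))
          px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
          f <- f + a * outer(sin(2 * pi * h * gy + py),
                             sin(2 * pi * h * gx + px))
        }
        vals[, , k] <- vals[, , k] + f
      }
    }
    vals
  }
  wu <- smooth_field(wind_mean[1], sd_of("wind"))
  wv <- smooth_field(wind_mean[2], sd_of("wind"))

  list(temp = env_series("temp", config$dates, ax$lat, ax$lon, temp),
       ndvi = env_series("ndvi", config$dates, ax$lat, ax$lon, ndvi),
       wind_u = env_series("wind_u", config$dates, ax$lat, ax$lon, wu),
       wind_v = env_series("wind_v", config$dates, ax$lat, ax$lon, wv))
}

#' Agent (simulated migrant) configuration
#'
#' Agents make one movement decision per `step_days`: K candidate
#' endpoints are drawn (exponential distance kernel; bearings from a
#' wrapped normal centred on the direction towards an attraction point),
#' and one is chosen with probability proportional to
#' `exp(beta . covariates)`. The attraction point sits at the melt-front
#' latitude offset by `coupling_offset_deg`: north of the front for
#' `"AHEAD"` (in snow), on it for `"ON_FRONT"`, south for `"BEHIND"`
#' (snow-free) -- the three front-position phenotypes.
#'
#' @param n_individuals Number of agents (>= 1).
#' @param n_steps Decisions per agent (>= 3).
#' @param step_days Days between decisions.
#' @param coupling One of `"AHEAD"`, `"ON_FRONT"`, `"BEHIND"`.
#' @param beta Named numeric selection coefficients
#'   `c(snow=, wind_support=, crosswind=)`.
#' @param step_mean_km Mean of the exponential step-length kernel (km).
#' @param K Candidates per decision (>= 2).
#' @param coupling_offset_deg Latitudinal offset of the attraction point
#'   from the front (degrees).
#' @param turn_sd_deg SD of the wrapped-normal candidate bearings around
#'   the attraction bearing (degrees).
#' @param seed Integer seed.
#' @return An `agent_config` list.
#' @export
agent_config <- function(n_individuals = 20, n_steps = 60, step_days = 1,
                         coupling = c("ON_FRONT", "AHEAD", "BEHIND"),
                         beta = c(snow = 0, wind_support = 0, crosswind = 0),
                         step_mean_km = 80, K = 10,
                         coupling_offset_deg = 3, turn_sd_deg = 40,
                         seed = 1L) {
  coupling <- match.arg(coupling)
  stopifnot(K >= 2, n_steps >= 3, n_individuals >= 1, step_mean_km > 0)
  beta_full <- c(snow = 0, wind_support = 0, crosswind = 0)
  beta_full[names(beta)] <- beta
  structure(list(n_individuals = as.integer(n_individuals),
                 n_steps = as.integer(n_steps), step_days = step_days,
                 coupling = coupling, beta = beta_full,
                 step_mean_km = step_mean_km, K = as.integer(K),
                 coupling_offset_deg = coupling_offset_deg,
                 turn_sd_deg = turn_sd_deg, seed = as.integer(seed)),
            class = "agent_config")
}

#' Simulate agent tracks over environmental fields
#'
#' Runs the decision process of [agent_config()] over a snow series (and
#' optional wind series), recording both the realised tracks
#' (Movebank-style) and, for every decision, the full candidate set with
#' its covariates and the chosen flag -- a ground-truth stratum set with
#' known selection coefficients.
#'
#' Covariate convention (matched by [build_strata()]): snow and wind are
#' evaluated at each candidate endpoint on the decision (start) date;
#' wind is decomposed along the start-to-candidate bearing.
#'
#' Agents whose candidate draws cannot be kept inside the grid are
#' truncated with a warning and kept only if at least 3 fixes remain.
#'
#' @param agents An [agent_config()].
#' @param rasters Named list of [env_series]; must contain `snow`, and
#'   `wind_u`/`wind_v` when wind coefficients are non-zero.
#' @param snow_cfg The [snow_front_config()] used to build the rasters
#'   (provides the front trajectory for the attraction point).
#' @param id_prefix Prefix for individual identifiers.
#' @return A list of class `sim_tracks`: `tracks` (Movebank-style data
#'   frame), `strata` (long ground-truth stratum data frame), `beta`
#'   (true coefficients), `config`.
#' @export
simulate_agents <- function(agents, rasters, snow_cfg,
                            id_prefix = agents$coupling) {
  stopifnot(inherits(agents, "agent_config"), "snow" %in% names(rasters))
  snow <- rasters$snow
  has_wind <- all(c("wind_u", "wind_v") %in% names(rasters))
  if (!has_wind && any(agents$beta[c("wind_support", "crosswind")] != 0))
    stop("wind coefficients set but no wind_u/wind_v series supplied")
  set.seed(agents$seed)
  dates <- snow$dates
  lat_rng <- range(snow$lat); lon_rng <- range(snow$lon)
  offset <- switch(agents$coupling, AHEAD = agents$coupling_offset_deg,
                   ON_FRONT = 0, BEHIND = -agents$coupling_offset_deg)
  rate <- 1 / agents$step_mean_km
  K <- agents$K
  trk <- list(); strat <- list(); si <- 0L
  for (a in seq_len(agents$n_individuals)) {
    id <- sprintf("%s_%02d", id_prefix, a)
    lat0 <- min(max(front_latitude(snow_cfg, dates[1]) + offset +
                      stats::rnorm(1, 0, 0.5), lat_rng[1]), lat_rng[2])
    lon0 <- stats::runif(1, lon_rng[1] + 0.1 * diff(lon_rng),
                         lon_rng[2] - 0.1 * diff(lon_rng))
    pos <- c(lon0, lat0)
    fixes <- data.frame(lon = pos[1], lat = pos[2], date = dates[1])
    truncated <- FALSE
    for (s in seq_len(agents$n_steps)) {
      date_s <- dates[1] + (s - 1) * agents$step_days
      if (date_s > dates[length(dates)]) break
      target_lat <- min(max(front_latitude(snow_cfg, date_s) + offset,
                            lat_rng[1]), lat_rng[2])
      bias <- bearing_deg(pos[1], pos[2], pos[1] + 1e-6, target_lat)
      cand <- .draw_candidates(pos, bias, rate, agents$turn_sd_deg, K,
                               lon_rng, lat_rng)
      if (is.null(cand)) { truncated <- TRUE; break }
      pts <- data.frame(lon = cand[, "lon"], lat = cand[, "lat"],
                        date = date_s)
      xsnow <- as.numeric(annotate_points(pts, snow, quiet = TRUE))
      if (has_wind) {
        wu <- as.numeric(annotate_points(pts, rasters$wind_u, quiet = TRUE))
        wv <- as.numeric(annotate_points(pts, rasters$wind_v, quiet = TRUE))
        wd <- wind_decompose(wu, wv, cand[, "bearing"])
      } else {
        wd <- data.frame(wind_support = rep(0, K), crosswind = rep(0, K))
      }
      eta <- agents$beta["snow"] * xsnow +
        agents$beta["wind_support"] * wd$wind_support +
        agents$beta["crosswind"] * wd$crosswind
      p <- exp(eta - max(eta)); p <- p / sum(p)
      chosen <- sample.int(K, 1, prob = p)
      si <- si + 1L
      strat[[si]] <- data.frame(
        stratum = sprintf("%s_s%03d", id, s), individual = id, step = s,
        date = date_s, candidate = seq_len(K),
        case = as.integer(seq_len(K) == chosen),
        lon0 = pos[1], lat0 = pos[2],
        lon = cand[, "lon"], lat = cand[, "lat"],
        bearing = cand[, "bearing"], dist_km = cand[, "dist"],
        snow = xsnow, wind_support = wd$wind_support,
        crosswind = wd$crosswind)
      pos <- unname(c(cand[chosen, "lon"], cand[chosen, "lat"]))
      fixes <- rbind(fixes, data.frame(lon = pos[1], lat = pos[2],
                                       date = date_s + agents$step_days))
    }
    if (truncated && nrow(fixes) < 3) {
      warning(sprintf("agent %s left the grid after %d fixes; dropped",
                      id, nrow(fixes)))
      next
    }
    if (truncated)
      warning(sprintf("agent %s left the grid; track truncated to %d fixes",
                      id, nrow(fixes)))
    trk[[id]] <- data.frame(
      `individual-local-identifier` = id,
      timestamp = format(as.POSIXct(paste(fixes$date, "12:00:00"),
                                    tz = "UTC"), "%Y-%m-%d %H:%M:%S"),
      `location-long` = fixes$lon, `location-lat` = fixes$lat,
      `sensor-type` = "gps", `argos-lc` = NA_character_,
      check.names = FALSE)
  }
  structure(list(tracks = do.call(rbind, c(trk, list(make.row.names = FALSE))),
                 strata = do.call(rbind, c(strat, list(make.row.names = FALSE))),
                 beta = agents$beta, config = agents),
            class = "sim_tracks")
}

# K in-grid candidates: exponential distances, wrapped-normal bearings.
# NULL if the retry cap is exhausted (agent cornered at the grid edge).
.draw_candidates <- function(pos, bias_bearing, rate, turn_sd, K,
                             lon_rng, lat_rng, max_try = 100L) {
  out <- matrix(NA_real_, K, 3, dimnames = list(NULL, c("lon", "lat", "dist")))
  bearings <- numeric(K)
  for (j in seq_len(K)) {
    ok <- FALSE
    for (tr in seq_len(max_try)) {
      d <- stats::rexp(1, rate)
      b <- (bias_bearing + stats::rnorm(1, 0, turn_sd)) %% 360
      dest <- destination_point(pos[1], pos[2], b, d)
      if (dest[1, "lon"] >= lon_rng[1] && dest[1, "lon"] <= lon_rng[2] &&
          dest[1, "lat"] >= lat_rng[1] && dest[1, "lat"] <= lat_rng[2]) {
        out[j, ] <- c(dest[1, "lon"], dest[1, "lat"], d)
        bearings[j] <- b
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  cbind(out, bearing = bearings)
}

#' Snow fraction in a neighbourhood of occupied locations
#'
#' Mean snow cover around each point on the point's own date: with
#' `radius_km = 0` (default) the nearest-cell value, otherwise the mean
#' over all cells whose centres lie within the radius. The radius is the
#' spatial scale at which occupancy figures (e.g. per-phenotype percent
#' snow cover) are computed; it is exposed rather than fixed because
#' occupancy percentages depend strongly on it.
#'
#' @param points Data frame with `lon`, `lat`, `date`.
#' @param snow A binary snow [env_series].
#' @param radius_km Neighbourhood radius in km.
#' @return Numeric vector of per-point snow fractions (NA off-grid).
#' @export
occupied_snow_fraction <- function(points, snow, radius_km = 0) {
  if (radius_km <= 0)
    return(as.numeric(annotate_points(points, snow, quiet = TRUE)))
  grid <- expand.grid(lat = snow$lat, lon = snow$lon,
                      KEEP.OUT.ATTRS = FALSE)
  out <- rep(NA_real_, nrow(points))
  for (i in seq_len(nrow(points))) {
    k <- match(as.Date(points$date[i]), snow$dates)
    if (is.na(k)) next
    d <- haversine_km(points$lon[i], points$lat[i], grid$lon, grid$lat)
    sel <- d <= radius_km
    if (any(sel)) out[i] <- mean(snow$values[, , k][sel])
  }
  out
}

#' Write a simulated scenario to disk
#'
#' Tracks as Movebank-style CSV, ground-truth strata as long CSV, and the
#' true coefficients plus configuration as a sidecar JSON.
#'
#' @param sim A `sim_tracks` object from [simulate_agents()].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_sim_tracks <- function(sim, dir, stem = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(stem, "_tracks.csv"))
  p2 <- file.path(dir, paste0(stem, "_strata.csv"))
  p3 <- file.path(dir, paste0(stem, "_truth.json"))
  utils::write.csv(sim$tracks, p1, row.names = FALSE)
  utils::write.csv(sim$strata, p2, row.names = FALSE)
  jsonlite::write_json(list(beta = as.list(sim$beta),
                            config = unclass(sim$config)),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(tracks = p1, strata = p2, truth = p3))
}
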