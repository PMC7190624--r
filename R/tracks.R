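# Movebank-style track ingestion, Argos quality filtering, fixed-interval
# burst resampling and step geometry.

ARGOS_CLASS_ORDER <- c("3", "2", "1", "0", "A", "B", "Z")  # best to worst

.col_aliases <- list(
  individual = c("individual-local-identifier", "individual.local.identifier",
                 "individual", "id"),
  timestamp = c("timestamp", "study-local-timestamp"),
  lon = c("location-long", "location.long", "lon", "longitude"),
  lat = c("location-lat", "location.lat", "lat", "latitude"),
  sensor = c("sensor-type", "sensor.type", "sensor"),
  argos_class = c("argos-lc", "argos.lc", "argos_class", "lc"))

.find_col <- function(nms, key, required = TRUE) {
  hit <- intersect(.col_aliases[[key]], nms)
  if (length(hit) == 0) {
    if (required)
      stop(sprintf("missing required column '%s'", .col_aliases[[key]][1]),
           call. = FALSE)
    return(NA_character_)
  }
  hit[1]
}

#' Read Movebank-style tracks
#'
#' Reads a delimited text file with Movebank-style columns
#' (`individual-local-identifier`, `timestamp` (ISO-8601 UTC),
#' `location-long`, `location-lat`, optional `sensor-type`, `argos-lc`)
#' into a track set: one track per individual-year. Rows with
#' unparseable coordinates or timestamps are dropped with a logged
#' count; exact duplicate individual+timestamp rows keep the first.
#'
#' @param path Path to a CSV file.
#' @return A `trackset`: data frame with columns `individual`, `year`,
#'   `timestamp`, `lon`, `lat`, `sensor`, `argos_class`, ordered by
#'   individual and time, with drop counts in attribute `log`.
#' @export
read_tracks <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty track file: ", path)
  nms <- names(raw)
  ci <- .find_col(nms, "individual"); ct <- .find_col(nms, "timestamp")
  cx <- .find_col(nms, "lon"); cy <- .find_col(nms, "lat")
  cs <- .find_col(nms, "sensor", required = FALSE)
  cc <- .find_col(nms, "argos_class", required = FALSE)
  ts <- as.POSIXct(raw[[ct]], tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(raw[[cx]]))
  lat <- suppressWarnings(as.numeric(raw[[cy]]))
  ok <- !is.na(ts) & !is.na(lon) & !is.na(lat) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon < 180
  n_bad <- sum(!ok)
  df <- data.frame(
    individual = as.character(raw[[ci]]),
    timestamp = ts, lon = lon, lat = lat,
    sensor = if (!is.na(cs)) toupper(as.character(raw[[cs]])) else "GPS",
    argos_class = if (!is.na(cc)) as.character(raw[[cc]]) else NA_character_,
    stringsAsFactors = FALSE)[ok, ]
  df <- df[order(df$individual, df$timestamp), ]
  dup <- duplicated(df[c("individual", "timestamp")])
  n_dup <- sum(dup)
  df <- df[!dup, ]
  df$year <- as.integer(format(df$timestamp, "%Y"))
  rownames(df) <- NULL
  if (n_bad + n_dup > 0)
    message(sprintf("read_tracks: dropped %d unparseable row(s), %d duplicate timestamp(s)",
                    n_bad, n_dup))
  structure(df[c("individual", "year", "timestamp", "lon", "lat",
                 "sensor", "argos_class")],
            log = list(n_read = nrow(raw), n_unparseable = n_bad,
                       n_duplicate = n_dup, n_kept = nrow(df)),
            class = c("trackset", "data.frame"))
}

#' Filter track fixes by Argos location class
#'
#' Removes Argos fixes with a location class worse than `min_class`
#' (classes ordered 3 > 2 > 1 > 0 > A > B > Z; the default keeps classes
#' 3 and 2, i.e. positional error under roughly 500 m). GPS fixes are
#' never filtered. Individual-years left with fewer than 3 fixes are
#' dropped with a warning.
#'
#' @param trackset A `trackset` from [read_tracks()].
#' @param min_class Worst acceptable Argos class (default `"2"`).
#' @return The filtered `trackset`, with counts appended to the `log`
#'   attribute.
#' @export
filter_quality <- function(trackset, min_class = "2") {
  rank_min <- match(as.character(min_class), ARGOS_CLASS_ORDER)
  if (is.na(rank_min)) stop("unknown Argos class: ", min_class)
  is_argos <- trackset$sensor == "ARGOS"
  rank <- match(trackset$argos_class, ARGOS_CLASS_ORDER)
  keep <- !is_argos | (!is.na(rank) & rank <= rank_min)
  n_class <- sum(!keep)
  out <- trackset[keep, ]
  key_all <- unique(paste(trackset$individual, trackset$year))
  key <- paste(out$individual, out$year)
  small <- union(names(which(table(key) < 3)), setdiff(key_all, key))
  if (length(small) > 0) {
    warning(sprintf("%d individual-year track(s) left with < 3 fixes; dropped",
                    length(small)))
    out <- out[!(key %in% small), ]
  }
  rownames(out) <- NULL
  lg <- attr(trackset, "log")
  lg$n_class_filtered <- n_class
  lg$n_small_tracks_dropped <- length(small)
  lg$n_after_filter <- nrow(out)
  structure(out, log = lg, class = c("trackset", "data.frame"))
}

#' Resample a track into fixed-interval bursts
#'
#' Greedy forward scan implementing the step-length resampling rule:
#' starting from an anchor fix, fixes closer in time than
#' `step_days - tolerance_days` are removed; the first fix inside
#' `[step_days - tolerance_days, step_days + tolerance_days]` extends
#' the current burst; if the first fix at or beyond the lower bound
#' overshoots the upper bound, the burst is closed and a new one starts
#' there. Bursts with fewer than 2 fixes are discarded. The operation is
#' idempotent at fixed parameters.
#'
#' @param track Data frame for one individual-year with `timestamp`
#'   (POSIXct), `lon`, `lat` (a single-track `trackset` subset works).
#' @param step_days Target step interval in days (typically 1, 3 or 5).
#' @param tolerance_days Acceptance half-window; default 10% of
#'   `step_days`.
#' @return List of burst data frames; each has attribute `step_days` and
#'   a `burst` id column.
#' @export
resample_steps <- function(track, step_days,
                           tolerance_days = 0.1 * step_days) {
  stopifnot(step_days > 0, tolerance_days >= 0, tolerance_days < step_days)
  track <- track[order(track$timestamp), ]
  n <- nrow(track)
  if (n == 0) return(list())
  tdays <- as.numeric(difftime(track$timestamp, track$timestamp[1],
                               units = "days"))
  lo <- step_days - tolerance_days
  hi <- step_days + tolerance_days
  bursts <- list(); cur <- 1L; anchor <- 1L
  j <- 2L
  while (j <= n) {
    dt <- tdays[j] - tdays[anchor]
    if (dt < lo) {
      j <- j + 1L                       # too close: remove fix
    } else if (dt <= hi) {
      cur <- c(cur, j); anchor <- j; j <- j + 1L
    } else {                            # gap: close burst, start new one
      bursts[[length(bursts) + 1L]] <- cur
      cur <- j; anchor <- j; j <- j + 1L
    }
  }
  bursts[[length(bursts) + 1L]] <- cur
  bursts <- Filter(function(ix) length(ix) >= 2, bursts)
  out <- lapply(seq_along(bursts), function(b) {
    df <- track[bursts[[b]], , drop = FALSE]
    df$burst <- b
    rownames(df) <- NULL
    attr(df, "step_days") <- step_days
    df
  })
  out
}

#' Step geometry of a burst
#'
#' Computes, for consecutive fix pairs, the great-circle step length
#' (haversine, mean Earth radius 6371 km), the heading (initial bearing,
#' degrees clockwise from north) and the turn angle (signed smallest
#' difference between consecutive headings, in (-180, 180]; `NA` for the
#' first step). Coincident consecutive fixes give length 0 and carry the
#' previous step's heading, flagged in `zero_length`.
#'
#' @param burst A burst data frame (>= 2 fixes) from [resample_steps()].
#' @return Data frame of steps: `individual`, `year`, `burst`, `step`,
#'   `t0`, `t1`, `lon0`, `lat0`, `lon1`, `lat1`, `length_km`,
#'   `heading`, `turn`, `zero_length`.
#' @export
step_geometry <- function(burst) {
  n <- nrow(burst)
  stopifnot(n >= 2)
  i0 <- seq_len(n - 1); i1 <- i0 + 1
  len <- haversine_km(burst$lon[i0], burst$lat[i0],
                      burst$lon[i1], burst$lat[i1])
  hd <- bearing_deg(burst$lon[i0], burst$lat[i0],
                    burst$lon[i1], burst$lat[i1])
  zero <- len < 1e-9
  hd[zero] <- NA_real_
  # carry heading over zero-length steps
  for (k in seq_along(hd))
    if (is.na(hd[k]) && k > 1) hd[k] <- hd[k - 1]
  turn <- c(NA_real_, angle_diff_deg(hd[-1], hd[-length(hd)]))
  data.frame(
    individual = if ("individual" %in% names(burst)) burst$individual[i0] else NA,
    year = if ("year" %in% names(burst)) burst$year[i0] else NA,
    burst = if ("burst" %in% names(burst)) burst$burst[i0] else 1L,
    step = i0,
    t0 = burst$timestamp[i0], t1 = burst$timestamp[i1],
    lon0 = burst$lon[i0], lat0 = burst$lat[i0],
    lon1 = burst$lon[i1], lat1 = burst$lat[i1],
    length_km = len, heading = hd, turn = turn, zero_length = zero)
}

#' Split a trackset into individual-year tracks
#'
#' @param trackset A `trackset`.
#' @return Named list of single-track data frames (`individual_year`).
#' @export
split_tracks <- function(trackset) {
  key <- paste(trackset$individual, trackset$year, sep = "_")
  lapply(split(as.data.frame(trackset), key), function(df) {
    rownames(df) <- NULL
    df
  })
}
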