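# First-passage-time profile and spring-migration extraction.
#
# FPT here is forward-only: for each fix, the time until the trajectory
# (linearly interpolated between fixes) first moves beyond the radius,
# searching forward from that fix.

#' First passage time profile
#'
#' For each fix, the time (days) until the forward trajectory first
#' exits a circle of `radius_km` centred on that fix. The crossing time
#' is interpolated linearly in distance between the bracketing fixes.
#' Fixes whose remaining trajectory never exits the circle get `NA`.
#'
#' @param track Single-track data frame with `timestamp`, `lon`, `lat`
#'   (>= 3 fixes).
#' @param radius_km Circle radius in km (> 0).
#' @return An `fpt_profile`: data frame `fix`, `timestamp`, `lon`,
#'   `lat`, `fpt_days`; attribute `radius_km`. Warns when no fix ever
#'   exits the circle.
#' @export
first_passage_time <- function(track, radius_km) {
  stopifnot(radius_km > 0)
  track <- track[order(track$timestamp), ]
  n <- nrow(track)
  if (n < 3) stop("first_passage_time needs >= 3 fixes")
  tdays <- as.numeric(difftime(track$timestamp, track$timestamp[1],
                               units = "days"))
  fpt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d_prev <- 0
    if (i < n) for (j in (i + 1):n) {
      d_j <- haversine_km(track$lon[i], track$lat[i],
                          track$lon[j], track$lat[j])
      if (d_j > radius_km) {
        denom <- d_j - d_prev
        f <- if (denom > 0) (radius_km - d_prev) / denom else 0
        t_cross <- tdays[j - 1] + f * (tdays[j] - tdays[j - 1])
        fpt[i] <- t_cross - tdays[i]
        break
      }
      d_prev <- d_j
    }
  }
  if (all(is.na(fpt)))
    warning("no fix ever exits the radius; all FPT undefined")
  structure(data.frame(fix = seq_len(n), timestamp = track$timestamp,
                       lon = track$lon, lat = track$lat, fpt_days = fpt),
            radius_km = radius_km, class = c("fpt_profile", "data.frame"))
}

#' Default FPT threshold from the log-FPT bimodality valley
#'
#' Migratory tracks typically show two log-FPT modes: short passage
#' times while travelling, long ones while stationary. The threshold is
#' placed at the density minimum between the two largest modes; with
#' fewer than two modes the median is used.
#'
#' @param fpt_profile An `fpt_profile`.
#' @return Threshold in days.
#' @export
fpt_threshold <- function(fpt_profile) {
  v <- fpt_profile$fpt_days
  v <- v[!is.na(v) & v > 0]
  if (length(v) < 5) return(stats::median(v))
  lv <- log(v)
  d <- stats::density(lv)
  ix <- seq(2, length(d$y) - 1)
  peaks <- ix[d$y[ix] > d$y[ix - 1] & d$y[ix] > d$y[ix + 1]]
  if (length(peaks) < 2) return(exp(stats::median(lv)))
  top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
  valley_ix <- seq(top2[1], top2[2])
  exp(d$x[valley_ix[which.min(d$y[valley_ix])]])
}

#' Extract the spring migration segment
#'
#' Takes the longest contiguous run of fixes whose FPT lies below the
#' threshold (fast, directed movement; undefined FPT counts as above
#' threshold) and clips it to a spring month window. Returns an empty
#' segment with a warning when no fix is below threshold.
#'
#' @param track The track used to build `fpt_profile`.
#' @param fpt_profile An `fpt_profile` from [first_passage_time()].
#' @param fpt_threshold_days Threshold in days; default from
#'   [fpt_threshold()].
#' @param spring_months Inclusive month window (default March-June).
#' @return List of class `migration_segment`: `segment` (track rows),
#'   `start`, `end` (dates, `NA` if empty), `threshold_days`.
#' @export
extract_migration <- function(track, fpt_profile,
                              fpt_threshold_days = fpt_threshold(fpt_profile),
                              spring_months = c(3, 6)) {
  track <- track[order(track$timestamp), ]
  months <- as.integer(format(fpt_profile$timestamp, "%m"))
  in_window <- months >= spring_months[1] & months <= spring_months[2]
  fast <- !is.na(fpt_profile$fpt_days) &
    fpt_profile$fpt_days < fpt_threshold_days & in_window
  if (!any(fast)) {
    warning("no fixes below the FPT threshold inside the spring window")
    return(structure(list(segment = track[0, ], start = as.Date(NA),
                          end = as.Date(NA),
                          threshold_days = fpt_threshold_days),
                     class = "migration_segment"))
  }
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  ix <- seq(starts[best], ends[best])
  seg <- track[ix, , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(segment = seg,
                 start = as.Date(min(seg$timestamp)),
                 end = as.Date(max(seg$timestamp)),
                 threshold_days = fpt_threshold_days),
            class = "migration_segment")
}

#' @export
print.migration_segment <- function(x, ...) {
  cat(sprintf("<migration_segment> %d fixes, %s .. %s (FPT threshold %.2f d)\n",
              nrow(x$segment), format(x$start), format(x$end),
              x$threshold_days))
  invisible(x)
}
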