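# Spherical geometry on a mean-radius Earth (R = 6371 km).

EARTH_RADIUS_KM <- 6371.0

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. All arguments are
#' recycled to a common length.
#'
#' @param lon1,lat1 Start coordinates, decimal degrees (WGS84 lon/lat).
#' @param lon2,lat2 End coordinates, decimal degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- p2 - p1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Initial bearing between points
#'
#' @inheritParams haversine_km
#' @return Initial (forward) bearing in degrees clockwise from geographic
#'   north, in \[0, 360).
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  (rad2deg(atan2(y, x)) + 360) %% 360
}

#' Destination point along a great circle
#'
#' @param lon,lat Start coordinates, decimal degrees.
#' @param bearing Bearing in degrees clockwise from north.
#' @param dist_km Distance in kilometres.
#' @return A two-column matrix with columns `lon`, `lat`.
#' @export
destination_point <- function(lon, lat, bearing, dist_km) {
  delta <- dist_km / EARTH_RADIUS_KM
  theta <- deg2rad(bearing)
  p1 <- deg2rad(lat); l1 <- deg2rad(lon)
  p2 <- asin(sin(p1) * cos(delta) + cos(p1) * sin(delta) * cos(theta))
  l2 <- l1 + atan2(sin(theta) * sin(delta) * cos(p1),
                   cos(delta) - sin(p1) * sin(p2))
  lon2 <- (rad2deg(l2) + 540) %% 360 - 180
  cbind(lon = lon2, lat = rad2deg(p2))
}

# Signed smallest angular difference a - b, mapped to (-180, 180].
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
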