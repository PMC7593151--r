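#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371 km. At the scale of a
#' coastal receiver array (tens to a few hundred km) the spherical
#' approximation is accurate to well under 0.5%, far below the granularity
#' of any distance threshold used in track segmentation.
#'
#' @param lat1,lon1 Origin coordinates in decimal degrees (vectorised).
#' @param lat2,lon2 Destination coordinates in decimal degrees.
#' @return Distance in kilometres, non-negative, symmetric in its arguments.
#' @examples
#' gc_distance(54, 8, 55, 8) # one degree of latitude, ~111.2 km
#' @export
gc_distance <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(a, 1)
  EARTH_RADIUS_KM * 2 * asin(sqrt(a))
}

EARTH_RADIUS_KM <- 6371

#' Initial great-circle bearing
#'
#' Forward azimuth of the great circle from the first point to the second,
#' in degrees clockwise from north, in `[0, 360)`.
#'
#' @inheritParams gc_distance
#' @return Bearing in degrees; error if origin and destination coincide.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  if (any(lat1 == lat2 & lon1 == lon2)) {
    stop("bearing undefined for coincident points")
  }
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  (atan2(y, x) * 180 / pi) %% 360
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180)) {
    stop("invalid latitude/longitude")
  }
  invisible(TRUE)
}
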