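# Shared helpers: spherical geometry, local metric frame, small utilities.

EARTH_RADIUS_M <- 6371000
M_PER_DEG_LAT <- pi * EARTH_RADIUS_M / 180  # 111194.93 m

#' Great-circle distance between lon/lat points
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorised over the
#' point pairs.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in metres.
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90),
            all(abs(lon1) <= 180), all(abs(lon2) <= 180))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = EARTH_RADIUS_M)
}

# Equirectangular ("projected Euclidean") approximation; adequate at
# sub-kilometre scales, exposed so the two distance readings can be compared.
planar_distance <- function(lon1, lat1, lon2, lat2) {
  mlat <- (lat1 + lat2) / 2
  dx <- (lon2 - lon1) * M_PER_DEG_LAT * cos(mlat * pi / 180)
  dy <- (lat2 - lat1) * M_PER_DEG_LAT
  sqrt(dx^2 + dy^2)
}

# Local metric frame anchored at `origin` (lon/lat): x metres east, y metres
# north. Used by the synthetic generators so nominal metre dimensions stay
# consistent with haversine distances at city scales.
local_to_lonlat <- function(x, y, origin) {
  lat <- origin[2] + y / M_PER_DEG_LAT
  lon <- origin[1] + x / (M_PER_DEG_LAT * cos(origin[2] * pi / 180))
  cbind(lon = lon, lat = lat)
}

lonlat_to_local <- function(lon, lat, origin) {
  y <- (lat - origin[2]) * M_PER_DEG_LAT
  x <- (lon - origin[1]) * M_PER_DEG_LAT * cos(origin[2] * pi / 180)
  cbind(x = x, y = y)
}

#' Percentage share, rounded for reporting
#'
#' Convenience for coverage statements such as "this city's users are 41.6%
#' of the national panel".
#'
#' @param part,total Nonnegative counts, `total > 0`.
#' @param digits Decimal places to round to (default 1).
#' @return `round(100 * part / total, digits)`.
#' @export
percentage_share <- function(part, total, digits = 1) {
  stopifnot(total > 0, part >= 0)
  round(100 * part / total, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
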