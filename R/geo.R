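# Geographic primitives shared by the movement and oceanography stages.
# All distances in km, all coordinates decimal degrees WGS84 unless noted.

#' Mean Earth radius (km)
#'
#' Fixed constant used by every great-circle computation in the package so
#' that distances are reproducible across platforms.
#' @export
EARTH_RADIUS_KM <- 6371.0

.check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude outside [-180, 180]", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance between points (haversine)
#'
#' Vectorised haversine distance on a sphere of radius
#' [EARTH_RADIUS_KM]. Used for trip distances ("total horizontal
#' Great Circle distance") and everywhere a geographic distance is needed.
#'
#' @param lon1,lat1,lon2,lat2 coordinates, decimal degrees.
#' @return distance in km, same length as the longest input.
#' @examples
#' haversine_km(0, 0, 1, 0)   # ~111.19 km, one degree along the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  .check_lonlat(lon1, lat1); .check_lonlat(lon2, lat2)
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  # clamp guards rounding at antipodes
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Project points to a local planar system (azimuthal equidistant)
#'
#' Projects lon/lat to km east/north about `origin`. Distance from the
#' origin is preserved exactly; distortion away from the origin grows with
#' range, so callers keep points within a few hundred km (shelf-scale
#' foraging trips). Inverse is [unproject_local()].
#'
#' @param lon,lat coordinates, decimal degrees.
#' @param origin c(lon, lat) of the projection centre.
#' @return data.frame with columns `x`, `y` (km east / north of origin).
#' @export
project_local <- function(lon, lat, origin) {
  .check_lonlat(lon, lat); .check_lonlat(origin[1], origin[2])
  r <- pi / 180
  lam <- lon * r; phi <- lat * r
  lam0 <- origin[1] * r; phi0 <- origin[2] * r
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  if (any(cosc <= -1 + 1e-12))
    stop("point antipodal to projection origin", call. = FALSE)
  c_ang <- acos(cosc)
  # k = c / sin(c); -> 1 as c -> 0
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  data.frame(x = x, y = y)
}

#' Inverse of [project_local()]
#'
#' @param x,y planar km east/north of `origin`.
#' @param origin c(lon, lat) of the projection centre.
#' @return data.frame with columns `lon`, `lat`.
#' @export
unproject_local <- function(x, y, origin) {
  r <- pi / 180
  lam0 <- origin[1] * r; phi0 <- origin[2] * r
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_KM
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  lat <- ifelse(rho < 1e-12, phi0,
                asin(cosc * sin(phi0) + y * sinc * cos(phi0) / rho))
  lon <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sinc,
                             rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  out <- data.frame(lon = lon / r, lat = lat / r)
  out$lon <- ((out$lon + 180) %% 360) - 180
  out
}
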