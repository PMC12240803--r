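#' Great-circle distance between points on a spherical Earth
#'
#' Haversine distance between two sets of longitude/latitude coordinates on a
#' sphere. All landscape edge weights in the package derive from this
#' distance; the default radius (6371 km, the mean Earth radius) is used
#' throughout unless overridden.
#'
#' @param a,b Numeric vectors `c(lon, lat)` in decimal degrees, or two-column
#'   matrices of such coordinates (recycled row-wise against each other).
#' @param radius_km Sphere radius in kilometres.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_distance(c(0, 0), c(90, 0))  # quarter great circle
#' @export
great_circle_distance <- function(a, b, radius_km = 6371) {
  a <- to_coord_matrix(a)
  b <- to_coord_matrix(b)
  check_lonlat(a)
  check_lonlat(b)
  geosphere::distHaversine(a, b, r = radius_km)
}

to_coord_matrix <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) {
    m <- as.matrix(p)[, 1:2, drop = FALSE]
  } else {
    m <- matrix(as.numeric(p), ncol = 2)
  }
  storage.mode(m) <- "double"
  m
}

check_lonlat <- function(m) {
  if (anyNA(m) || any(!is.finite(m))) {
    stop("coordinates must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(m[, 1] < -180 | m[, 1] > 180)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  if (any(m[, 2] < -90 | m[, 2] > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  invisible(m)
}

#' Elevation-adjusted (slope) distance between two cells
#'
#' Extends a horizontal great-circle distance to the slope distance by
#' Pythagoras, treating the elevation difference (converted to km) as the
#' vertical leg. Equals the horizontal distance when the elevations agree.
#'
#' @param horizontal_km Horizontal distance in km (vectorised).
#' @param elev_a_m,elev_b_m Endpoint elevations in metres.
#' @return Slope distance in km, always `>= horizontal_km`.
#' @examples
#' elevation_adjusted_distance(3, 0, 4000)  # 3-4-5 triangle -> 5 km
#' @export
elevation_adjusted_distance <- function(horizontal_km, elev_a_m, elev_b_m) {
  if (any(horizontal_km < 0)) stop("horizontal_km must be non-negative", call. = FALSE)
  dz_km <- (elev_b_m - elev_a_m) / 1000
  sqrt(horizontal_km^2 + dz_km^2)
}

#' Summarize a set of geographic points as a single point
#'
#' One point is returned unchanged; two points give their great-circle
#' midpoint; three or more give the spherical centroid (mean of unit vectors
#' renormalized to the sphere). Used to reduce multiple tip occurrences to a
#' single representative coordinate.
#'
#' @param points Two-column matrix/data.frame of (lon, lat) in degrees.
#' @return Numeric `c(lon, lat)`.
#' @export
point_summary <- function(points) {
  m <- to_coord_matrix(points)
  check_lonlat(m)
  n <- nrow(m)
  if (n < 1) stop("at least one point required", call. = FALSE)
  if (n == 1) return(c(lon = m[1, 1], lat = m[1, 2]))
  if (n == 2) {
    if (is_antipodal(m[1, ], m[2, ])) {
      stop("great-circle midpoint of an antipodal pair is ambiguous", call. = FALSE)
    }
    mid <- geosphere::midPoint(m[1, ], m[2, ])
    return(c(lon = mid[1, 1], lat = mid[1, 2]))
  }
  v <- lonlat_to_unit(m)
  ctr <- colMeans(v)
  nrm <- sqrt(sum(ctr^2))
  if (nrm < 1e-12) {
    stop("points are balanced around the sphere centre; centroid is ambiguous", call. = FALSE)
  }
  unit_to_lonlat(ctr / nrm)
}

is_antipodal <- function(a, b, tol = 1e-9) {
  va <- lonlat_to_unit(matrix(a, ncol = 2))
  vb <- lonlat_to_unit(matrix(b, ncol = 2))
  sum(va * vb) < -1 + tol
}

lonlat_to_unit <- function(m) {
  lon <- m[, 1] * pi / 180
  lat <- m[, 2] * pi / 180
  cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

unit_to_lonlat <- function(v) {
  lon <- atan2(v[2], v[1]) * 180 / pi
  lat <- asin(max(-1, min(1, v[3]))) * 180 / pi
  if (lon >= 180) lon <- lon - 360
  c(lon = lon, lat = lat)
}
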