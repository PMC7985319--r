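#' Great-circle distance on a spherical Earth
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Coordinates are
#' decimal degrees (WGS-84 treated as spherical). Both arguments may be
#' single points `c(lon, lat)` or two-column matrices; they are recycled
#' row-wise against each other.
#'
#' @param p1,p2 numeric vectors `c(lon, lat)` or matrices with columns
#'   (lon, lat), in decimal degrees.
#' @return distances in km.
#' @export
great_circle_distance <- function(p1, p2) {
  p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  n <- max(nrow(p1), nrow(p2))
  p1 <- p1[rep_len(seq_len(nrow(p1)), n), , drop = FALSE]
  p2 <- p2[rep_len(seq_len(nrow(p2)), n), , drop = FALSE]
  check_coords(p1); check_coords(p2)
  lam1 <- p1[, 1] * pi / 180; phi1 <- p1[, 2] * pi / 180
  lam2 <- p2[, 1] * pi / 180; phi2 <- p2[, 2] * pi / 180
  dphi <- phi2 - phi1
  dlam <- lam2 - lam1
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  unname(2 * EARTH_RADIUS_KM * asin(sqrt(a)))
}

# coerce c(lon, lat) vectors / data frames to an unnamed 2-column matrix
as_point_matrix <- function(p) {
  m <- if (is.null(dim(p))) matrix(p, nrow = 1) else as.matrix(p)
  dimnames(m) <- NULL
  m
}

#' Pairwise great-circle distance matrix
#'
#' @param coords matrix or data frame with columns (lon, lat), degrees.
#' @return symmetric `n x n` matrix of distances in km.
#' @export
great_circle_matrix <- function(coords) {
  coords <- as_point_matrix(coords)[, 1:2, drop = FALSE]
  check_coords(coords)
  phi <- coords[, 2] * pi / 180
  lam <- coords[, 1] * pi / 180
  n <- nrow(coords)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + (cos(phi) %o% cos(phi)) * sin(dlam / 2)^2
  a[a < 0] <- 0; a[a > 1] <- 1
  d <- 2 * EARTH_RADIUS_KM * asin(sqrt(a))
  diag(d) <- 0
  d
}

#' Final bearing of the great-circle path between two points
#'
#' The bearing of the path at the destination point, in degrees clockwise
#' from north, wrapped to [0, 360). Used only to assign point pairs to
#' direction sectors for directional variograms.
#'
#' @param p1,p2 points `c(lon, lat)` (or matrices), decimal degrees; must be
#'   distinct.
#' @return bearings in degrees, in [0, 360).
#' @export
bearing <- function(p1, p2) {
  p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  check_coords(p1); check_coords(p2)
  n <- max(nrow(p1), nrow(p2))
  i1 <- rep_len(seq_len(nrow(p1)), n); i2 <- rep_len(seq_len(nrow(p2)), n)
  if (any(rowSums(abs(p1[i1, , drop = FALSE] - p2[i2, , drop = FALSE])) == 0))
    stop("bearing undefined for coincident points")
  b <- geosphere::finalBearing(p1, p2, a = EARTH_RADIUS_KM * 1000, f = 0)
  unname((b + 360) %% 360)
}

check_coords <- function(coords) {
  coords <- as_point_matrix(coords)
  lon <- coords[, 1]; lat <- coords[, 2]
  if (anyNA(lon) || anyNA(lat)) stop("coordinates contain missing values")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon >= 360)) stop("longitude outside valid range")
  invisible(TRUE)
}
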