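#' Universal Transverse Mercator projection specification
#'
#' Builds the projection used to place geocodes on a planar metric grid.
#' The default is UTM zone 18N on the GRS80 ellipsoid (NAD83), the local
#' system for the New York metropolitan area; any UTM zone or a custom
#' central meridian can be configured.
#'
#' @param zone UTM zone number (1-60), or `NULL` to supply `lon0` directly.
#' @param datum `"NAD83"` (GRS80 ellipsoid) or `"WGS84"`. The two differ by
#'   well under a millimetre in the ellipsoid constants.
#' @param lon0 Central meridian in decimal degrees; derived from `zone`
#'   when omitted.
#' @return A `bizscape_crs` list with ellipsoid constants, scale factor and
#'   false easting/northing.
#' @export
utm_crs <- function(zone = 18, datum = c("NAD83", "WGS84"), lon0 = NULL) {
  datum <- match.arg(datum)
  a <- 6378137
  f <- if (datum == "NAD83") 1 / 298.257222101 else 1 / 298.257223563
  if (is.null(lon0)) {
    stopifnot(is.numeric(zone), zone >= 1, zone <= 60)
    lon0 <- -183 + 6 * zone
  }
  structure(list(a = a, f = f, k0 = 0.9996, lon0 = lon0,
                 x0 = 500000, y0 = 0, zone = zone, datum = datum),
            class = "bizscape_crs")
}

# Krueger series coefficients in the third flattening n, to n^4 (errors far
# below 1 mm anywhere inside a UTM zone).
tm_constants <- function(crs) {
  f <- crs$f
  n <- f / (2 - f)
  A <- crs$a / (1 + n) * (1 + n^2 / 4 + n^4 / 64)
  alpha <- c(n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180,
             13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440,
             61 * n^3 / 240 - 103 * n^4 / 140,
             49561 * n^4 / 161280)
  beta <- c(n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360,
            n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440,
            17 * n^3 / 480 - 37 * n^4 / 840,
            4397 * n^4 / 161280)
  delta <- c(2 * n - 2 * n^2 / 3 - 2 * n^3 + 116 * n^4 / 45,
             7 * n^2 / 3 - 8 * n^3 / 5 - 227 * n^4 / 45,
             56 * n^3 / 15 - 136 * n^4 / 35,
             4279 * n^4 / 630)
  e <- sqrt(f * (2 - f))
  list(n = n, A = A, alpha = alpha, beta = beta, delta = delta, e = e)
}

#' Project geographic coordinates to planar metres
#'
#' Forward transverse Mercator projection (Krueger series) from geographic
#' longitude/latitude to easting/northing in the configured system.
#'
#' @param lon,lat Numeric vectors of decimal degrees.
#' @param crs A [utm_crs()] specification.
#' @return A tibble with columns `x` (easting) and `y` (northing), metres.
#' @export
project_lonlat <- function(lon, lat, crs = utm_crs()) {
  stopifnot(length(lon) == length(lat))
  if (length(lon) == 0L) return(tibble(x = double(), y = double()))
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE)) {
    abort("Coordinates outside valid WGS84 ranges",
          class = "bizscape_error_input")
  }
  k <- tm_constants(crs)
  phi <- lat * pi / 180
  lam <- (lon - crs$lon0) * pi / 180
  if (any(abs(lon - crs$lon0) > 5, na.rm = TRUE)) {
    warn("Some coordinates fall well outside the projection zone; results are extrapolated")
  }
  t <- sinh(atanh(sin(phi)) - k$e * atanh(k$e * sin(phi)))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  j <- 1:4
  xi <- xi_p
  eta <- eta_p
  for (i in j) {
    xi <- xi + k$alpha[i] * sin(2 * i * xi_p) * cosh(2 * i * eta_p)
    eta <- eta + k$alpha[i] * cos(2 * i * xi_p) * sinh(2 * i * eta_p)
  }
  tibble(x = crs$x0 + crs$k0 * k$A * eta,
         y = crs$y0 + crs$k0 * k$A * xi)
}

#' Inverse projection from planar metres to geographic coordinates
#'
#' @param x,y Numeric vectors of easting/northing in metres.
#' @inheritParams project_lonlat
#' @return A tibble with columns `lon` and `lat` in decimal degrees.
#' @export
unproject_xy <- function(x, y, crs = utm_crs()) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(tibble(lon = double(), lat = double()))
  k <- tm_constants(crs)
  xi <- (y - crs$y0) / (crs$k0 * k$A)
  eta <- (x - crs$x0) / (crs$k0 * k$A)
  xi_p <- xi
  eta_p <- eta
  for (i in 1:4) {
    xi_p <- xi_p - k$beta[i] * sin(2 * i * xi) * cosh(2 * i * eta)
    eta_p <- eta_p - k$beta[i] * cos(2 * i * xi) * sinh(2 * i * eta)
  }
  chi <- asin(sin(xi_p) / cosh(eta_p))
  phi <- chi
  for (i in 1:4) {
    phi <- phi + k$delta[i] * sin(2 * i * chi)
  }
  lam <- atan2(sinh(eta_p), cos(xi_p))
  tibble(lon = crs$lon0 + lam * 180 / pi,
         lat = phi * 180 / pi)
}

#' Project geocodes and round to the spatial deduplication grid
#'
#' Projects WGS84/NAD83 geographic coordinates to the planar system and
#' rounds each axis to the nearest 10 m (ties away from zero). Identical
#' rounded coordinates are what downstream collapsing treats as "the same
#' location", absorbing sub-10 m jitter between geocoding engines.
#'
#' @param lat,lon Numeric vectors of decimal degrees (note the
#'   latitude-first argument order conventional for geocoder output).
#' @param crs A [utm_crs()] specification.
#' @param grid Rounding grid in metres (default 10).
#' @return A tibble with integer-valued columns `x` and `y`, multiples of
#'   `grid`.
#' @export
project_and_round <- function(lat, lon, crs = utm_crs(), grid = 10) {
  xy <- project_lonlat(lon, lat, crs)
  tibble(x = round_to_grid(xy$x, grid), y = round_to_grid(xy$y, grid))
}
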