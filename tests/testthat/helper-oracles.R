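# Independent oracles, deliberately implemented with different
# algorithms than the package code they check.

# Transverse Mercator forward projection, Snyder (USGS PP 1395) series.
snyder_utm <- function(lon, lat, crs = utm_crs()) {
  a <- crs$a; f <- crs$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- crs$k0
  phi <- lat * pi / 180
  lam <- (lon - crs$lon0) * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- cos(phi) * lam
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
              (35 * e2^3 / 3072) * sin(6 * phi))
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                   (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) +
    crs$x0
  y <- k0 * (M + N * tan(phi) *
               (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                  (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720)) +
    crs$y0
  data.frame(x = x, y = y)
}

# Classic ray-casting point-in-polygon (single ring, matrix nx2).
ray_cast_inside <- function(px, py, ring) {
  xs <- ring[, 1]; ys <- ring[, 2]
  nv <- nrow(ring)
  if (xs[1] == xs[nv] && ys[1] == ys[nv]) nv <- nv - 1
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    cnt <- 0L
    j <- nv
    for (i in seq_len(nv)) {
      if ((ys[i] > py[p]) != (ys[j] > py[p])) {
        xint <- xs[i] + (py[p] - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
        if (px[p] < xint) cnt <- cnt + 1L
      }
      j <- i
    }
    inside[p] <- (cnt %% 2L) == 1L
  }
  inside
}

# Brute-force best geocode candidate: score every candidate with an
# explicit tuple and scan for the minimum.
brute_force_best <- function(df) {
  pri <- c(gold_local = 1, commercial_point = 2, commercial_street = 3,
           vendor_supplied = 4)
  best <- 1L
  for (i in seq_len(nrow(df))[-1]) {
    a <- df[i, ]; b <- df[best, ]
    key_a <- c(pri[[a$source]], match(a$source, sort(names(pri))),
               a$lat, a$lon)
    key_b <- c(pri[[b$source]], match(b$source, sort(names(pri))),
               b$lat, b$lon)
    cmp <- key_a - key_b
    nz <- which(cmp != 0)
    if (length(nz) && cmp[nz[1]] < 0) best <- i
  }
  df[best, ]
}

# Brute-force grouping counts via base R, including the collapse rule
# (distinct rounded coordinates within a cell).
brute_force_counts <- function(points) {
  cell <- paste(points$geography_id, points$category, points$year,
                sep = "\r")
  raw <- table(cell)
  site <- paste(points$x, points$y, sep = ",")
  collapsed <- tapply(site, cell, function(s) length(unique(s)))
  data.frame(cell = names(raw), raw = as.integer(raw),
             collapsed = as.integer(collapsed[names(raw)]),
             stringsAsFactors = FALSE)
}
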