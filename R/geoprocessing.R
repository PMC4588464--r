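#' Merge geocode candidates by source priority
#'
#' Several geocoding engines can return coordinates for the same address;
#' a fixed a-priori priority decides which one is kept: the locally
#' maintained gold-standard engine beats a commercial point-level match,
#' which beats a commercial interpolated street-segment match, with the
#' delivery-supplied coordinates as last resort ([source_priority()]).
#' Ties within a tier break deterministically by source name, then by
#' (lat, lon) lexicographic order.
#'
#' @param candidates Tibble of geocode candidates with columns `duns_id`,
#'   `role`, `move_index`, `source`, `lat`, `lon`, `precision`; may mix
#'   many addresses — merging happens within each
#'   (`duns_id`, `role`, `move_index`) group.
#' @return Tibble with one winning candidate per group.
#' @export
merge_geocodes <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    abort("merge_geocodes: no candidates supplied (vendor fallback expected upstream)",
          class = "bizscape_error_input")
  }
  if (any(abs(candidates$lat) > 90) || any(abs(candidates$lon) > 180)) {
    abort("Candidate coordinates outside WGS84 bounds",
          class = "bizscape_error_input")
  }
  candidates |>
    mutate(.rank = source_rank(.data$source)) |>
    arrange(.data$duns_id, .data$role, .data$move_index,
            .data$.rank, .data$source, .data$lat, .data$lon) |>
    group_by(.data$duns_id, .data$role, .data$move_index) |>
    slice_head(n = 1) |>
    ungroup() |>
    select(-".rank")
}

#' Restrict location assignments by geocoding precision
#'
#' Keeps assignments geocoded at or above a minimum precision on the
#' scale of [precision_levels()] and reports what was excluded, counted
#' by year and source. The default minimum, `"street_segment"`, mirrors
#' the common analytic choice of "street level or higher": point, block
#' face and street segment pass; block group, tract centroid and zip
#' centroids are excluded.
#'
#' @param assignments Tibble with at least `year`, `source`, `precision`.
#' @param minimum Weakest acceptable precision label.
#' @return List with `kept` (tibble), `excluded` (tibble) and `report`
#'   (excluded counts by year and source).
#' @export
filter_by_precision <- function(assignments, minimum = "street_segment") {
  stopifnot(length(minimum) == 1L)
  min_rank <- precision_rank(minimum)
  r <- precision_rank(assignments$precision)
  kept <- assignments[r <= min_rank, , drop = FALSE]
  excluded <- assignments[r > min_rank, , drop = FALSE]
  report <- excluded |>
    count(.data$year, .data$source, name = "n_excluded") |>
    arrange(.data$year, .data$source)
  list(kept = kept, excluded = excluded, report = report)
}

#' Per-year precision distribution
#'
#' Summarises how geocoding precision is distributed over calendar years
#' — the table behind "share of businesses not geocoded better than the
#' zip level" style quality reporting.
#'
#' @param assignments Tibble with `year` and `precision`.
#' @return Tibble `year`, `precision`, `n`, `share` (within year).
#' @export
precision_by_year <- function(assignments) {
  assignments |>
    count(.data$year, .data$precision) |>
    group_by(.data$year) |>
    mutate(share = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(precision = factor(.data$precision, levels = precision_levels())) |>
    arrange(.data$year, .data$precision)
}

# ---- study region ------------------------------------------------------

#' Build a study region from planar polygon rings
#'
#' @param features Named list: each element is a list of polygon rings,
#'   each ring a two-column (x, y) matrix in planar metres. Interior
#'   rings (holes) are handled by even-odd parity.
#' @return A `bizscape_region` object.
#' @export
region_from_rings <- function(features) {
  stopifnot(is.list(features), length(features) > 0,
            !is.null(names(features)))
  feats <- lapply(names(features), function(id) {
    rings <- lapply(features[[id]], function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2)
      storage.mode(r) <- "double"
      r
    })
    list(id = id, rings = rings)
  })
  structure(list(features = feats), class = "bizscape_region")
}

#' Read study-region polygons from GeoJSON
#'
#' Reads Polygon / MultiPolygon features (WGS84 longitude/latitude, as
#' GeoJSON mandates) and projects them into the planar system so that
#' point-in-region tests run in the same coordinates as the location
#' assignments. Feature ids come from a `properties` field named `id`,
#' `name` or `GEOID` (first found), else `feature_<i>`.
#'
#' @param path GeoJSON file.
#' @param crs [utm_crs()] projection for the planar system.
#' @return A `bizscape_region`.
#' @export
read_region_geojson <- function(path, crs = utm_crs()) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties %||% list()
    id <- props$id %||% props$name %||% props$GEOID %||%
      paste0("feature_", i)
    geom <- f$geometry %||% f
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    abort(paste0("Unsupported GeoJSON geometry: ", geom$type),
                          class = "bizscape_error_input"))
    rings <- list()
    for (poly in polys) {
      for (ring in poly) {
        m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        xy <- project_lonlat(m[, 1], m[, 2], crs)
        rings[[length(rings) + 1L]] <- cbind(xy$x, xy$y)
      }
    }
    out[[as.character(id)]] <- rings
  }
  region_from_rings(out)
}

# Boundary-inclusive point-in-rings test, even-odd rule across rings.
points_in_rings <- function(x, y, rings, eps = 1e-9) {
  inside <- rep(FALSE, length(x))
  boundary <- rep(FALSE, length(x))
  for (ring in rings) {
    xs <- ring[, 1]; ys <- ring[, 2]
    nv <- length(xs)
    if (xs[1] == xs[nv] && ys[1] == ys[nv]) nv <- nv - 1L
    j <- nv
    for (i in seq_len(nv)) {
      x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
      # on-segment test
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2))
        d2 <- (x1 + t * dx - x)^2 + (y1 + t * dy - y)^2
        boundary <- boundary | d2 <= eps^2
      } else {
        boundary <- boundary | ((x - x1)^2 + (y - y1)^2 <= eps^2)
      }
      # even-odd crossing (half-open rule avoids double-counting vertices)
      crosses <- ((y1 > y) != (y2 > y)) &
        (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses & !is.na(crosses))
      j <- i
    }
  }
  inside | boundary
}

#' Assign points to region features
#'
#' Boundary-inclusive point-in-polygon containment; a point on a feature
#' edge counts as inside. Points falling in no feature get `NA`.
#'
#' @param x,y Planar coordinates (same system as the region).
#' @param region A `bizscape_region`.
#' @return Character vector of feature ids (first containing feature).
#' @export
locate_in_region <- function(x, y, region) {
  stopifnot(inherits(region, "bizscape_region"))
  out <- rep(NA_character_, length(x))
  for (f in region$features) {
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- points_in_rings(x[todo], y[todo], f$rings)
    out[todo][hit] <- f$id
  }
  out
}

#' Exclude locations outside the study region
#'
#' Registry deliveries scoped to a region still contain locations that
#' geocode outside it (relocations away, headquarters of local branches);
#' those are excluded from analysis. Boundary points count as inside.
#'
#' @param assignments Tibble with planar `x`, `y`.
#' @param region A `bizscape_region` (must be non-empty).
#' @return List with `kept` and `excluded` tibbles; `kept` gains a
#'   `geography_id` column naming the containing feature.
#' @export
exclude_out_of_region <- function(assignments, region) {
  if (!inherits(region, "bizscape_region") ||
      length(region$features) == 0L) {
    abort("A non-empty study region is required",
          class = "bizscape_error_input")
  }
  gid <- locate_in_region(assignments$x, assignments$y, region)
  kept <- assignments[!is.na(gid), , drop = FALSE]
  kept$geography_id <- gid[!is.na(gid)]
  list(kept = kept, excluded = assignments[is.na(gid), , drop = FALSE])
}
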