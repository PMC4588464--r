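#' Geocoding precision levels, best first
#'
#' The ordered precision scale used throughout the package: rooftop/parcel
#' point matches, then block face, interpolated street segment, block group,
#' census tract centroid, and finally zip-code centroid. Block face sits
#' between point and street segment.
#'
#' @return Character vector of precision labels, most precise first.
#' @export
precision_levels <- function() {
  c("point", "block_face", "street_segment", "block_group",
    "tract_centroid", "zip")
}

#' Geocode source tiers, highest priority first
#'
#' Priority order used when merging candidates for the same address:
#' a locally maintained gold-standard engine beats a commercial point-level
#' match, which beats a commercial street-segment (interpolated) match, and
#' the coordinates shipped with the registry delivery are the fallback of
#' last resort.
#'
#' @return Character vector of source labels, highest priority first.
#' @export
source_priority <- function() {
  c("gold_local", "commercial_point", "commercial_street", "vendor_supplied")
}

precision_rank <- function(precision) {
  r <- match(precision, precision_levels())
  if (anyNA(r)) {
    bad <- unique(precision[is.na(r)])
    abort(paste0("Unknown precision level(s): ", paste(bad, collapse = ", ")),
          class = "bizscape_error_precision")
  }
  r
}

source_rank <- function(source) {
  r <- match(source, source_priority())
  if (anyNA(r)) {
    bad <- unique(source[is.na(r)])
    abort(paste0("Unknown geocode source(s): ", paste(bad, collapse = ", ")),
          class = "bizscape_error_source")
  }
  r
}

#' Round planar coordinates to a grid
#'
#' Rounds to the nearest multiple of `grid` metres, with exact half-grid
#' ties rounded away from zero (base `round()` would round to even).
#'
#' @param v Numeric vector of planar coordinates in metres.
#' @param grid Grid spacing in metres (default 10).
#' @return Numeric vector of multiples of `grid`.
#' @examples
#' round_to_grid(c(583960.4, 4507523.7))   # 583960, 4507520
#' round_to_grid(15)                       # tie: away from zero -> 20
#' round_to_grid(-15)                      # -20
#' @export
round_to_grid <- function(v, grid = 10) {
  stopifnot(is.numeric(v), length(grid) == 1L, grid > 0)
  sign(v) * floor(abs(v) / grid + 0.5) * grid
}

is_valid_duns <- function(x) {
  grepl("^[0-9]{9}$", x)
}

is_valid_zip5 <- function(x) {
  grepl("^[0-9]{5}$", x)
}

#' @noRd
check_years <- function(year, what = "year") {
  if (!is.numeric(year) || anyNA(year) || any(year != floor(year))) {
    abort(paste0(what, " must be whole calendar years"),
          class = "bizscape_error_input")
  }
  invisible(as.integer(year))
}

# Run an expression with a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic code in the package funnels through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed from a master seed; keeps independent
# stages decoupled while remaining reproducible. Result stays below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103515245 + stream * 12345) %% 2147483647
}

new_stage_log <- function() {
  structure(list(), class = "bizscape_log")
}

log_stage <- function(log, stage, records_in, records_out, ...) {
  entry <- c(list(stage = stage,
                  records_in = as.integer(records_in),
                  records_out = as.integer(records_out)),
             list(...))
  log[[length(log) + 1L]] <- entry
  log
}

write_jsonl <- function(log, path) {
  lines <- vapply(log, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
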