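cand_row <- function(source, lat = 40.7, lon = -74.0,
                     precision = "point") {
  tibble::tibble(duns_id = "111111111", role = "most_recent",
                 move_index = NA_integer_, source = source,
                 lat = lat, lon = lon, precision = precision)
}

test_that("merge_geocodes equals brute-force priority over all subsets", {
  sources <- source_priority()
  base <- dplyr::bind_rows(lapply(seq_along(sources), function(i) {
    cand_row(sources[i], lat = 40.7 + i / 100, lon = -74 - i / 100)
  }))
  for (mask in 1:15) {
    subset <- base[which(bitwAnd(mask, 2^(0:3)) > 0), ]
    got <- merge_geocodes(subset)
    want <- brute_force_best(as.data.frame(subset))
    expect_equal(got$source, want$source, info = paste("mask", mask))
    expect_equal(got$lat, want$lat, info = paste("mask", mask))
  }
})

test_that("merge_geocodes prefers the documented engine order", {
  expect_equal(merge_geocodes(dplyr::bind_rows(
    cand_row("gold_local"), cand_row("commercial_point")))$source,
    "gold_local")
  expect_equal(merge_geocodes(
    cand_row("commercial_street", precision = "street_segment"))$source,
    "commercial_street")
  expect_equal(merge_geocodes(dplyr::bind_rows(
    cand_row("vendor_supplied", precision = "zip")))$source,
    "vendor_supplied")
  # within-tier ties break on coordinates, deterministically
  two <- dplyr::bind_rows(cand_row("gold_local", lat = 40.8, lon = -74.1),
                          cand_row("gold_local", lat = 40.7, lon = -74.1))
  expect_equal(merge_geocodes(two)$lat, 40.7)
  expect_error(merge_geocodes(tibble::tibble()),
               class = "bizscape_error_input")
})

test_that("projection matches an independent Snyder implementation", {
  crs <- utm_crs()
  set.seed(1)
  lon <- runif(60, -77.9, -72.1)
  lat <- runif(60, 38, 44)
  mine <- project_lonlat(lon, lat, crs)
  oracle <- snyder_utm(lon, lat, crs)
  expect_lt(max(abs(mine$x - oracle$x)), 0.01)
  expect_lt(max(abs(mine$y - oracle$y)), 0.01)
  # inverse round-trips to the input coordinates
  back <- unproject_xy(mine$x, mine$y, crs)
  expect_lt(max(abs(back$lon - lon)), 1e-9)
  expect_lt(max(abs(back$lat - lat)), 1e-9)
  # coordinates far outside the zone still project, with a warning
  expect_warning(project_lonlat(-120, 40, crs), "zone")
})

test_that("10 m rounding is nearest with ties away from zero", {
  expect_equal(round_to_grid(c(583960.4, 4507523.7)),
               c(583960, 4507520))
  expect_equal(round_to_grid(583960), 583960)     # already on grid
  expect_equal(round_to_grid(c(15, 25, -15)), c(20, 30, -20))
  ll <- unproject_xy(583960, 4507520)
  expect_equal(as.numeric(project_and_round(ll$lat, ll$lon)),
               c(583960, 4507520))
})

test_that("precision filtering keeps 'street level or higher'", {
  asg <- tibble::tibble(
    year = 2000L, source = "gold_local",
    precision = c("point", "block_face", "street_segment", "block_group",
                  "tract_centroid", "zip"))
  res <- filter_by_precision(asg, "street_segment")
  expect_setequal(res$kept$precision,
                  c("point", "block_face", "street_segment"))
  expect_equal(sum(res$report$n_excluded), 3)
  expect_equal(nrow(filter_by_precision(asg, "zip")$excluded), 0)
  only <- tibble::tibble(year = 1L, source = "s",
                         precision = c("point", "zip"))
  expect_equal(filter_by_precision(only, "street_segment")$kept$precision,
               "point")
  expect_error(filter_by_precision(asg, "rooftop"),
               class = "bizscape_error_precision")
})

test_that("raising the precision minimum never increases the kept count", {
  set.seed(3)
  asg <- tibble::tibble(year = sample(1990:2010, 500, TRUE),
                        source = "vendor_supplied",
                        precision = sample(precision_levels(), 500, TRUE))
  kept <- vapply(precision_levels(),
                 function(m) nrow(filter_by_precision(asg, m)$kept),
                 numeric(1))
  expect_true(all(diff(kept) >= 0))  # weakest minimum last, keeps most
  expect_equal(kept[["zip"]], 500)
})

test_that("point-in-polygon matches a ray-casting oracle exactly", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  region <- region_from_rings(list(sq = list(square)))
  set.seed(11)
  px <- runif(1000, -0.5, 1.5)
  py <- runif(1000, -0.5, 1.5)
  got <- !is.na(locate_in_region(px, py, region))
  want <- ray_cast_inside(px, py, square)
  expect_identical(got, want)
})

test_that("region exclusion keeps boundary and centroid points", {
  square <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  region <- region_from_rings(list(sq = list(square)))
  asg <- tibble::tibble(x = c(5, 100, 0, 10, 5),
                        y = c(5, 100, 0, 5, 10))
  res <- exclude_out_of_region(asg, region)
  expect_equal(nrow(res$kept), 4)      # centroid + 3 boundary points
  expect_equal(res$excluded$x, 100)
  expect_equal(unique(res$kept$geography_id), "sq")
  empty_region <- structure(list(features = list()),
                            class = "bizscape_region")
  expect_error(exclude_out_of_region(asg, empty_region),
               class = "bizscape_error_input")
})

test_that("polygon holes and multiple features resolve correctly", {
  outer_ring <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  hole <- rbind(c(4, 4), c(6, 4), c(6, 6), c(4, 6), c(4, 4))
  region <- region_from_rings(list(donut = list(outer_ring, hole),
                                   east = list(outer_ring + 20)))
  expect_equal(locate_in_region(2, 2, region), "donut")
  expect_true(is.na(locate_in_region(5, 5, region)))  # inside the hole
  expect_equal(locate_in_region(25, 25, region), "east")
})

test_that("GeoJSON regions read, project and contain as expected", {
  crs <- utm_crs()
  ll <- unproject_xy(c(565000, 570000, 570000, 565000),
                     c(4492000, 4492000, 4496000, 4496000), crs)
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "countyA"),
    geometry = list(type = "Polygon", coordinates = list(
      lapply(c(1:4, 1), function(i) list(ll$lon[i], ll$lat[i])))))))
  path <- file.path(withr::local_tempdir(), "region.geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 12)
  region <- read_region_geojson(path, crs)
  expect_equal(locate_in_region(567000, 4494000, region), "countyA")
  expect_true(is.na(locate_in_region(580000, 4494000, region)))
})

test_that("vendor-only geocodes depress early-year kept counts", {
  p <- synth_params(n_establishments = 2500, seed = 37)
  g <- generate_registry(p)
  book <- suppressMessages(build_address_book(g$bundle))
  ym <- assign_yearly_locations(book, g$bundle$moves, g$bundle$years)
  keep_series <- function(cands) {
    best <- merge_geocodes(cands)
    asg <- ym |>
      dplyr::inner_join(best, by = c("duns_id", "role", "move_index"))
    filter_by_precision(asg, "street_segment")$kept |>
      dplyr::count(year, name = "kept")
  }
  vendor_only <- keep_series(g$bundle$vendor_geocodes)
  providers <- default_mock_providers(g$city, seed = 37)
  cands <- g$bundle$vendor_geocodes
  addr <- book |> dplyr::select(duns_id, role, move_index, line, zip5)
  for (prov in providers) cands <- dplyr::bind_rows(cands, prov(addr))
  merged <- keep_series(cands)
  cmp <- dplyr::inner_join(vendor_only, merged, by = "year",
                           suffix = c("_vendor", "_merged"))
  ratio <- cmp$kept_vendor / cmp$kept_merged
  early <- mean(ratio[cmp$year <= 1994])
  late <- mean(ratio[cmp$year >= 2006])
  expect_lt(early, late - 0.05)
  # the excluded-by-year share under vendor-only input declines over time
  vexcl <- merge_geocodes(g$bundle$vendor_geocodes)
  asg <- ym |>
    dplyr::inner_join(vexcl, by = c("duns_id", "role", "move_index"))
  shares <- precision_by_year(asg) |>
    dplyr::filter(precision == "zip")
  expect_gt(shares$share[shares$year == 1990],
            shares$share[shares$year == 2000])
  expect_gt(shares$share[shares$year == 2000],
            shares$share[shares$year == 2010])
})
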