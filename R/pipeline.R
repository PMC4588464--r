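#' Default mock provider set for synthetic runs
#'
#' Three pluggable geocoding providers over the synthetic city, one per
#' commercial tier: a gold-standard local engine and a commercial
#' point-level engine (both point precision), and a commercial
#' street-segment engine. Failure rates emulate engines declining to
#' match some addresses; seeds derive deterministically from `seed`.
#'
#' @param city A [synthetic_city()].
#' @param failure_rates Named numeric failure probabilities per tier.
#' @param seed Integer master seed.
#' @return Named list of provider functions (see [mock_provider()]).
#' @export
default_mock_providers <- function(city = synthetic_city(),
                                   failure_rates = c(gold_local = 0.05,
                                                     commercial_point = 0.10,
                                                     commercial_street = 0.05),
                                   seed = 1L) {
  out <- list()
  for (i in seq_along(failure_rates)) {
    src <- names(failure_rates)[i]
    out[[src]] <- mock_provider(city, source = src,
                                failure_rate = failure_rates[[i]],
                                seed = child_seed(seed, i))
  }
  # street-tier engines only resolve to street segments
  if ("commercial_street" %in% names(out)) {
    inner <- out$commercial_street
    out$commercial_street <- function(addresses) {
      res <- inner(addresses)
      res$precision <- "street_segment"
      res
    }
  }
  out
}

#' Assemble a pipeline configuration
#'
#' Validates everything up front — referenced files must exist, the
#' category config must load, the precision label must be known — so a
#' bad configuration fails before any stage runs.
#'
#' @param input One of: a `nets_registry`, a [synth_params()] object
#'   (the registry is generated), or a character vector of NETS-dialect
#'   file paths for [read_registry()].
#' @param out_dir Optional output directory; when set, every stage
#'   output is written as CSV with a seed provenance header, plus a JSON
#'   run report and a JSON-lines stage log.
#' @param definitions Category definitions: a path, a list, a
#'   `bizscape_categories` tibble, or `NULL` for the shipped template.
#' @param region Study region: a `bizscape_region`, a GeoJSON path, or
#'   `NULL` to skip out-of-region exclusion (single geography `"all"`).
#' @param providers Named list of geocoding provider functions, or
#'   `NULL` for delivery (vendor) geocodes only.
#' @param min_precision Weakest precision kept (see
#'   [filter_by_precision()]).
#' @param mode `"both"`, `"overall"` or `"yearly"` categorisation.
#' @param boundary Move-year boundary convention (see
#'   [assign_yearly_locations()]).
#' @param crs Planar projection, see [utm_crs()].
#' @param strict_estimated Treat imputed size values as missing.
#' @param seed Integer seed governing all pipeline randomness.
#' @return A validated `bizscape_config` list.
#' @export
pipeline_config <- function(input, out_dir = NULL, definitions = NULL,
                            region = NULL, providers = NULL,
                            min_precision = "street_segment",
                            mode = c("both", "overall", "yearly"),
                            boundary = c("move_year", "year_after"),
                            crs = utm_crs(), strict_estimated = FALSE,
                            seed = 1L) {
  mode <- match.arg(mode)
  boundary <- match.arg(boundary)
  if (is.character(input) && !all(file.exists(input))) {
    abort(paste0("Input file(s) not found: ",
                 paste(input[!file.exists(input)], collapse = ", ")),
          class = "bizscape_error_config")
  }
  if (is.character(definitions) && !file.exists(definitions)) {
    abort(paste0("Category definition file not found: ", definitions),
          class = "bizscape_error_config")
  }
  defs <- if (inherits(definitions, "bizscape_categories")) definitions
          else load_category_definitions(definitions)
  if (is.character(region)) {
    if (!file.exists(region)) {
      abort(paste0("Region file not found: ", region),
            class = "bizscape_error_config")
    }
    region <- read_region_geojson(region, crs)
  }
  precision_rank(min_precision)
  structure(list(input = input, out_dir = out_dir, definitions = defs,
                 region = region, providers = providers,
                 min_precision = min_precision, mode = mode,
                 boundary = boundary, crs = crs,
                 strict_estimated = strict_estimated,
                 seed = as.integer(seed)),
            class = "bizscape_config")
}

#' Run the full refinement pipeline
#'
#' Sequences the stages: registry ingest (or synthesis), comprehensive
#' address book, per-year location-role assignment, multi-provider
#' geocoding with priority merge and vendor fallback, planar projection
#' with 10 m rounding, out-of-region exclusion, precision filtering,
#' overall and/or yearly categorisation, co-location collapsing, count
#' tables and per-geography linear trends. Each stage's record counts
#' are logged; the run report carries the per-year precision
#' distribution and the category accounting totals.
#'
#' @param config A [pipeline_config()].
#' @return A `bizscape_run` object (list of stage outputs, report, log).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bizscape_config"))
  log <- new_stage_log()
  truth <- NULL
  city <- NULL

  # -- ingest
  if (inherits(config$input, "nets_registry")) {
    bundle <- config$input
  } else if (inherits(config$input, "bizscape_synth_params")) {
    gen <- generate_registry(config$input)
    bundle <- gen$bundle
    truth <- gen$truth
    city <- gen$city
  } else if (is.character(config$input)) {
    bundle <- read_registry(config$input)
  } else {
    abort("Unsupported pipeline input", class = "bizscape_error_config")
  }
  log <- log_stage(log, "ingest", nrow(bundle$establishments),
                   nrow(bundle$establishments),
                   business_years = nrow(bundle$years),
                   moves = nrow(bundle$moves))

  # -- address book and year map
  book <- build_address_book(bundle)
  log <- log_stage(log, "address_book", nrow(bundle$establishments),
                   nrow(book),
                   discrepancies = nrow(attr(book, "discrepancies")))
  year_map <- assign_yearly_locations(book, bundle$moves, bundle$years,
                                      boundary = config$boundary)
  log <- log_stage(log, "year_locations", nrow(bundle$years),
                   nrow(year_map))

  # -- geocoding: provider candidates + vendor fallback, priority merge
  candidates <- bundle$vendor_geocodes
  if (!is.null(config$providers)) {
    addr <- book |> select("duns_id", "role", "move_index", "line", "zip5")
    for (prov in config$providers) {
      candidates <- bind_rows(candidates, prov(addr))
    }
  }
  merged <- merge_geocodes(candidates)
  log <- log_stage(log, "geocode_merge", nrow(candidates), nrow(merged))

  # geocode of the role in force each year; for a non-mover whose first
  # and most-recent strings disagree, the most-recent geocode is used
  disc <- attr(book, "discrepancies")
  nm_disc <- if (nrow(disc)) {
    disc$duns_id[disc$check == "first vs most_recent"]
  } else character()
  lookup_role <- year_map |>
    mutate(geo_role = if_else(.data$role == "first" &
                                .data$duns_id %in% nm_disc,
                              "most_recent", .data$role))
  assignments <- lookup_role |>
    left_join(merged |>
                select("duns_id", geo_role = "role", "move_index",
                       "source", "lat", "lon", "precision"),
              by = c("duns_id", "geo_role", "move_index")) |>
    select("duns_id", "year", "role", "move_index", "source", "lat",
           "lon", "precision")
  ungeocoded <- sum(is.na(assignments$lat))
  if (ungeocoded > 0) {
    assignments <- assignments |> filter(!is.na(.data$lat))
  }
  xy <- project_and_round(assignments$lat, assignments$lon, config$crs)
  assignments <- bind_cols(assignments, xy)
  log <- log_stage(log, "project_round", nrow(year_map),
                   nrow(assignments), ungeocoded = ungeocoded)

  # -- region exclusion
  if (!is.null(config$region)) {
    reg <- exclude_out_of_region(assignments, config$region)
    in_region <- reg$kept
    excluded_region <- reg$excluded
  } else {
    in_region <- assignments |> mutate(geography_id = "all")
    excluded_region <- assignments[0, ]
  }
  log <- log_stage(log, "region_filter", nrow(assignments),
                   nrow(in_region), excluded = nrow(excluded_region))

  # -- precision filter
  pf <- filter_by_precision(in_region, config$min_precision)
  kept <- pf$kept
  log <- log_stage(log, "precision_filter", nrow(in_region), nrow(kept),
                   excluded = nrow(pf$excluded))

  # -- categorisation
  cats_overall <- NULL
  cats_yearly <- NULL
  if (config$mode %in% c("both", "overall")) {
    cats_overall <- categorize_overall(bundle, config$definitions,
                                       strict_estimated = config$strict_estimated)
    log <- log_stage(log, "categorize_overall",
                     nrow(bundle$establishments), nrow(cats_overall),
                     categorized = sum(cats_overall$category !=
                                         "uncategorized"))
  }
  if (config$mode %in% c("both", "yearly")) {
    cats_yearly <- categorize_yearly(bundle, config$definitions,
                                     strict_estimated = config$strict_estimated)
    log <- log_stage(log, "categorize_yearly", nrow(bundle$years),
                     nrow(cats_yearly))
  }

  # -- business-year points, counts, trends (overall-mode categories
  # drive the headline tables; yearly mode is the sensitivity track)
  year_span <- range(bundle$years$year)
  make_points <- function(cat_tbl, by_year) {
    if (by_year) {
      kept |>
        inner_join(cat_tbl |> select("duns_id", "year", "category"),
                   by = c("duns_id", "year"))
    } else {
      kept |>
        inner_join(cat_tbl |> select("duns_id", "category"),
                   by = "duns_id")
    }
  }
  points <- counts <- trends <- NULL
  counts_yearly <- NULL
  if (!is.null(cats_overall)) {
    points <- make_points(cats_overall, FALSE)
    counts <- count_by_geography(points |>
                                   filter(.data$category != "uncategorized"),
                                 years = year_span)
    trends <- fit_linear_trends(counts)
    log <- log_stage(log, "counts", nrow(points), nrow(counts))
  }
  if (!is.null(cats_yearly)) {
    points_yearly <- make_points(cats_yearly, TRUE)
    counts_yearly <- count_by_geography(points_yearly |>
                                          filter(.data$category !=
                                                   "uncategorized"),
                                        years = year_span)
  }

  # -- run report
  movers <- dplyr::n_distinct(bundle$moves$duns_id)
  report <- list(
    seed = config$seed,
    n_establishments = nrow(bundle$establishments),
    n_business_years = nrow(bundle$years),
    n_movers = movers,
    pct_movers = 100 * movers / nrow(bundle$establishments),
    precision_by_year = precision_by_year(in_region),
    category_totals = if (!is.null(cats_overall)) {
      cats_overall |> count(.data$category, name = "n") |>
        arrange(dplyr::desc(.data$n))
    },
    collapse_summary = if (!is.null(counts)) {
      counts |>
        group_by(.data$category) |>
        summarise(raw = sum(.data$raw), collapsed = sum(.data$collapsed),
                  reduction_pct = 100 * (1 - sum(.data$collapsed) /
                                           pmax(sum(.data$raw), 1)),
                  .groups = "drop")
    })

  run <- structure(
    list(config = config, bundle = bundle, truth = truth, city = city,
         book = book, year_map = year_map, assignments = assignments,
         kept = kept, excluded_region = excluded_region,
         excluded_precision = pf$excluded,
         categories_overall = cats_overall,
         categories_yearly = cats_yearly,
         points = points, counts = counts, counts_yearly = counts_yearly,
         trends = trends, report = report, log = log),
    class = "bizscape_run")

  if (!is.null(config$out_dir)) {
    write_run(run, config$out_dir)
  }
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- run$config$seed
  w <- function(x, name) {
    if (!is.null(x)) write_stage_csv(as_tibble(x), file.path(dir, name),
                                     seed = seed)
  }
  w(run$book |> select(-any_of("note")), "address_book.csv")
  w(run$year_map, "year_location.csv")
  w(run$kept, "locations.csv")
  w(bind_rows(run$excluded_region |> mutate(reason = "out_of_region"),
              run$excluded_precision |> mutate(reason = "precision")),
    "exclusions.csv")
  w(run$categories_overall, "assignments.csv")
  w(run$categories_yearly, "assignments_yearly.csv")
  w(run$counts, "counts.csv")
  w(run$trends, "trends.csv")
  report <- run$report
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  write_jsonl(run$log, file.path(dir, "log.jsonl"))
  invisible(dir)
}

#' @export
print.bizscape_run <- function(x, ...) {
  cat("<bizscape_run>\n")
  cat("  establishments:", x$report$n_establishments,
      sprintf("(%.1f%% movers)\n", x$report$pct_movers))
  cat("  geocoded business-years kept:", nrow(x$kept), "\n")
  if (!is.null(x$report$category_totals)) {
    nc <- sum(x$report$category_totals$category != "uncategorized")
    cat("  categories with members:", nc, "\n")
  }
  if (!is.null(x$trends)) {
    cat("  trend fits:", nrow(x$trends), "series\n")
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.bizscape_run <- function(x, ...) {
  tibble(n_establishments = x$report$n_establishments,
         n_business_years = x$report$n_business_years,
         pct_movers = x$report$pct_movers,
         n_kept_locations = nrow(x$kept),
         n_excluded_region = nrow(x$excluded_region),
         n_excluded_precision = nrow(x$excluded_precision),
         n_categorized = if (!is.null(x$categories_overall)) {
           sum(x$categories_overall$category != "uncategorized")
         } else NA_integer_,
         seed = x$config$seed)
}
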