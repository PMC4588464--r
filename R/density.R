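#' Collapse co-located same-category records
#'
#' Registries carry multiple concurrent records for what is effectively
#' one establishment (name variants, one LLC per practitioner at a
#' shared office). To avoid over-counting, records in the same category,
#' in the same year, at the same location — operationalised as identical
#' 10 m-rounded projected coordinates — are collapsed to a single
#' representative record, the lexicographically smallest DUNS number in
#' the group. Businesses in *different* categories at the same location
#' always remain distinct (shopping malls, medical office buildings).
#' The operation is idempotent.
#'
#' @param points Tibble of business-year points: `duns_id`, `year`,
#'   `category`, `x`, `y` (multiples of the rounding grid). Rows with
#'   category `"uncategorized"` are not meaningful to collapse and are
#'   dropped with a warning unless `include_uncategorized = TRUE`.
#' @param include_uncategorized Collapse within the uncategorized pool
#'   too, instead of dropping it.
#' @return List: `points` (collapsed tibble) and `map` (tibble
#'   `duns_id`, `year`, `representative` linking every input record to
#'   its surviving representative).
#' @export
collapse_colocated <- function(points, include_uncategorized = FALSE) {
  if (!include_uncategorized && any(points$category == "uncategorized")) {
    warn("Dropping uncategorized records before collapsing (set include_uncategorized = TRUE to keep them)")
    points <- points |> filter(.data$category != "uncategorized")
  }
  mapped <- points |>
    group_by(.data$category, .data$year, .data$x, .data$y) |>
    mutate(representative = min(.data$duns_id)) |>
    ungroup()
  list(points = mapped |>
         filter(.data$duns_id == .data$representative) |>
         select(-"representative"),
       map = mapped |> select("duns_id", "year", "representative"))
}

#' Count businesses per geography, category and year
#'
#' Exact group-by counts of business-year points, reported both raw and
#' after collapsing co-located same-category records. Cells with no
#' businesses are emitted as explicit zeros over the full year range so
#' the table is rectangular. Points without a geography are routed to
#' the sentinel geography `"unassigned"` and reported.
#'
#' @param points Tibble with `duns_id`, `year`, `category`, `x`, `y`,
#'   `geography_id`.
#' @param years Integer vector of calendar years the table must span
#'   (default: the years present).
#' @param include_uncategorized Passed to [collapse_colocated()].
#' @return A `bizscape_counts` tibble: `geography_id`, `category`,
#'   `year`, `raw`, `collapsed`.
#' @export
count_by_geography <- function(points, years = NULL,
                               include_uncategorized = FALSE) {
  if (nrow(points) == 0L) {
    out <- tibble(geography_id = character(), category = character(),
                  year = integer(), raw = integer(), collapsed = integer())
    return(structure(out, class = c("bizscape_counts", class(out))))
  }
  if (is.null(points$geography_id)) {
    abort("points need a geography_id column (see exclude_out_of_region())",
          class = "bizscape_error_input")
  }
  unassigned <- is.na(points$geography_id)
  if (any(unassigned)) {
    inform(paste0("count_by_geography: ", sum(unassigned),
                  " point(s) without geography routed to 'unassigned'"))
    points$geography_id[unassigned] <- "unassigned"
  }
  if (!include_uncategorized) {
    points <- points |> filter(.data$category != "uncategorized")
  }
  years <- check_years(years %||% sort(unique(points$year)))
  years <- seq(min(years), max(years))

  raw <- points |>
    count(.data$geography_id, .data$category, .data$year, name = "raw")
  # collapsed count per cell = distinct occupied sites: same-site
  # same-category same-year records contribute one record
  coll <- points |>
    group_by(.data$geography_id, .data$category, .data$year) |>
    summarise(collapsed = dplyr::n_distinct(.data$x, .data$y),
              .groups = "drop")
  grid <- tidyr::expand_grid(
    distinct(points, .data$geography_id, .data$category),
    year = years)
  out <- grid |>
    left_join(raw, by = c("geography_id", "category", "year")) |>
    left_join(coll, by = c("geography_id", "category", "year")) |>
    mutate(raw = tidyr::replace_na(.data$raw, 0L),
           collapsed = tidyr::replace_na(.data$collapsed, 0L)) |>
    arrange(.data$geography_id, .data$category, .data$year)
  structure(out, class = c("bizscape_counts", class(out)))
}

#' Fit per-geography linear time trends
#'
#' Ordinary least squares of the business count on calendar year, fitted
#' separately for every geography-by-category series (the per-county
#' "spaghetti plot" lines). Closed-form slope, intercept and slope
#' standard error; series need at least two distinct years.
#'
#' @param counts A `bizscape_counts` table (or any tibble with
#'   `geography_id`, `category`, `year` and a count column).
#' @param response Which count to model: `"collapsed"` (default) or
#'   `"raw"`.
#' @return A `bizscape_trends` tibble: `geography_id`, `category`,
#'   `slope` (businesses per year), `intercept`, `slope_se`, `n_years`,
#'   `r_squared`.
#' @export
fit_linear_trends <- function(counts, response = c("collapsed", "raw")) {
  response <- match.arg(response)
  df <- as_tibble(counts) |>
    rename(.count = all_of(response))
  bad <- df |>
    group_by(.data$geography_id, .data$category) |>
    summarise(ok = dplyr::n_distinct(.data$year) >= 2, .groups = "drop")
  if (!all(bad$ok)) {
    abort("Each geography-category series needs at least two distinct years",
          class = "bizscape_error_input")
  }
  out <- df |>
    group_by(.data$geography_id, .data$category) |>
    summarise(
      n_years = n(),
      sxx = sum((.data$year - mean(.data$year))^2),
      sxy = sum((.data$year - mean(.data$year)) *
                  (.data$.count - mean(.data$.count))),
      ybar = mean(.data$.count), xbar = mean(.data$year),
      syy = sum((.data$.count - mean(.data$.count))^2),
      .groups = "drop") |>
    mutate(slope = .data$sxy / .data$sxx,
           intercept = .data$ybar - .data$slope * .data$xbar,
           rss = pmax(.data$syy - .data$slope * .data$sxy, 0),
           slope_se = ifelse(.data$n_years > 2,
                             sqrt(.data$rss / (.data$n_years - 2) / .data$sxx),
                             NA_real_),
           r_squared = ifelse(.data$syy > 0,
                              1 - .data$rss / .data$syy, NA_real_)) |>
    select("geography_id", "category", "slope", "intercept", "slope_se",
           "n_years", "r_squared")
  structure(out, class = c("bizscape_trends", class(out)),
            response = response)
}

#' @exportS3Method generics::tidy
tidy.bizscape_trends <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.bizscape_trends <- function(x, ...) {
  tibble(n_series = nrow(x),
         n_geographies = dplyr::n_distinct(x$geography_id),
         n_categories = dplyr::n_distinct(x$category),
         median_slope = stats::median(x$slope),
         response = attr(x, "response") %||% "collapsed")
}

#' Spaghetti plot of per-geography category counts
#'
#' One line per geography for each category: the visual check that
#' aggregate trends are not driven by a single geography, with optional
#' overlaid least-squares trend lines.
#'
#' @param object A `bizscape_counts` table.
#' @param response `"collapsed"` or `"raw"`.
#' @param trend Overlay the fitted linear trend per series.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bizscape_counts <- function(object, response = c("collapsed", "raw"),
                                     trend = FALSE, ...) {
  response <- match.arg(response)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$year,
                                    y = .data[[response]],
                                    group = .data$geography_id,
                                    colour = .data$geography_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = "Year", y = paste(response, "count"),
                  colour = "Geography") +
    ggplot2::theme_minimal()
  if (trend) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, linewidth = 0.4,
                                  linetype = "dashed")
  }
  p
}

#' Compare raw, collapsed and yearly-mode totals for one category
#'
#' The sensitivity display for categorisation and collapsing decisions:
#' total counts over time under overall-mode raw, overall-mode
#' collapsed, and (optionally) yearly-mode classification.
#'
#' @param counts_overall A `bizscape_counts` from overall-mode points.
#' @param category Category label to display.
#' @param counts_yearly Optional `bizscape_counts` from yearly-mode
#'   points; its raw series is shown as "yearly".
#' @return A ggplot object.
#' @export
plot_category_sensitivity <- function(counts_overall, category,
                                      counts_yearly = NULL) {
  tot <- function(tbl, col, label) {
    tbl |>
      filter(.data$category == !!category) |>
      group_by(.data$year) |>
      summarise(count = sum(.data[[col]]), .groups = "drop") |>
      mutate(series = label)
  }
  df <- bind_rows(tot(counts_overall, "raw", "overall, raw"),
                  tot(counts_overall, "collapsed", "overall, collapsed"),
                  if (!is.null(counts_yearly))
                    tot(counts_yearly, "raw", "yearly, raw"))
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$count,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = category, x = "Year", y = "Businesses",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
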