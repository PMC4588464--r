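#' Load researcher-defined category definitions
#'
#' Categories are mutually exclusive business groupings (food stores,
#' restaurants, physical-activity venues, medical facilities, banks, ...)
#' defined by SIC code sets (exact 8-digit codes or `"5812*"` prefix
#' patterns), optional name include/exclude patterns matched on the
#' normalised company/trade name, optional size thresholds (employees,
#' sales) and an optional MET value for physical-activity venues. A
#' unique `priority` rank per definition resolves multi-category matches:
#' the lowest rank wins, so size-restricted definitions (large
#' supermarket) must rank above the residual categories they carve out
#' of (convenience/small grocery).
#'
#' A 25-category template with illustrative, non-canonical SIC sets ships
#' at `system.file("extdata", "categories_template.yaml", package =
#' "bizscape")`.
#'
#' @param source Path to a YAML/JSON file, or a list with a `categories`
#'   element.
#' @return Tibble with one row per definition (list-columns for pattern
#'   sets), validated; class `bizscape_categories`.
#' @export
load_category_definitions <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "categories_template.yaml",
                          package = "bizscape")
  }
  raw <- if (is.character(source)) yaml::read_yaml(source) else source
  cats <- raw$categories %||% raw
  defs <- purrr::map_dfr(cats, function(d) {
    tibble(name = d$name,
           priority = as.integer(d$priority),
           sic = list(as.character(d$sic %||% character())),
           name_include = list(as.character(d$name_include %||% character())),
           name_exclude = list(as.character(d$name_exclude %||% character())),
           min_employees = as.double(d$min_employees %||% NA),
           max_employees = as.double(d$max_employees %||% NA),
           min_sales = as.double(d$min_sales %||% NA),
           max_sales = as.double(d$max_sales %||% NA),
           met_value = as.double(d$met_value %||% NA))
  })
  if (anyNA(defs$priority) || anyDuplicated(defs$priority)) {
    abort("Category priority ranks must be present and unique",
          class = "bizscape_error_config")
  }
  if (anyDuplicated(defs$name)) {
    abort("Category names must be unique", class = "bizscape_error_config")
  }
  if (any(!is.na(defs$met_value) & defs$met_value <= 0)) {
    abort("met_value must be positive where present",
          class = "bizscape_error_config")
  }
  structure(arrange(defs, .data$priority),
            class = c("bizscape_categories", class(defs)))
}

match_sic_patterns <- function(sic, patterns) {
  if (length(patterns) == 0L) return(rep(FALSE, length(sic)))
  hit <- rep(FALSE, length(sic))
  for (p in patterns) {
    if (endsWith(p, "*")) {
      hit <- hit | startsWith(sic, substr(p, 1, nchar(p) - 1L))
    } else {
      hit <- hit | sic == p
    }
  }
  hit & !is.na(sic)
}

match_name_patterns <- function(name_norm, patterns) {
  if (length(patterns) == 0L) return(rep(FALSE, length(name_norm)))
  hit <- rep(FALSE, length(name_norm))
  for (p in patterns) {
    hit <- hit | stringr::str_detect(name_norm, stringr::regex(p,
                                                               ignore_case = TRUE))
  }
  hit & !is.na(name_norm)
}

#' Does an establishment match one category definition?
#'
#' The matching rule: the SIC matches the definition's code set (exact or
#' prefix) **or** a name-include pattern matches the normalised company
#' or trade name; **and** no name-exclude pattern matches; **and** every
#' size threshold the definition carries is satisfied. Missing size
#' fields fail a threshold-bearing definition — a store with unknown
#' employee count is never promoted into a size-restricted category.
#'
#' @param attrs Tibble (vectorised row-wise) with `sic`, `company_name`,
#'   `trade_name`, `sales`, `employees`. Names may be raw; they are
#'   normalised internally.
#' @param def One row of [load_category_definitions()].
#' @return Logical vector, one element per row of `attrs`.
#' @export
match_definition <- function(attrs, def) {
  n <- nrow(attrs)
  name_norm <- normalize_name(paste(
    if_else(is.na(attrs$company_name), "", attrs$company_name),
    if_else(is.na(attrs$trade_name %||% rep(NA_character_, n)), "",
            attrs$trade_name %||% rep(NA_character_, n))))
  name_norm[name_norm == ""] <- NA_character_
  hit <- match_sic_patterns(attrs$sic, def$sic[[1]]) |
    match_name_patterns(name_norm, def$name_include[[1]])
  hit <- hit & !match_name_patterns(name_norm, def$name_exclude[[1]])
  chk <- function(value, bound, op) {
    ifelse(is.na(value), FALSE, op(value, bound))
  }
  if (!is.na(def$min_employees)) hit <- hit & chk(attrs$employees, def$min_employees, `>=`)
  if (!is.na(def$max_employees)) hit <- hit & chk(attrs$employees, def$max_employees, `<=`)
  if (!is.na(def$min_sales)) hit <- hit & chk(attrs$sales, def$min_sales, `>=`)
  if (!is.na(def$max_sales)) hit <- hit & chk(attrs$sales, def$max_sales, `<=`)
  hit
}

#' Assign establishments to mutually exclusive categories
#'
#' Applies every definition in priority order; among all definitions an
#' establishment matches, the lowest priority rank wins, and an
#' establishment matching none is `"uncategorized"`. The result records
#' which rule fired (`sic` or `name`) and the deciding SIC.
#'
#' @param attrs Tibble with `sic`, `company_name`, `trade_name`, `sales`,
#'   `employees` (one row per unit being classified; extra columns pass
#'   through).
#' @param definitions From [load_category_definitions()].
#' @return `attrs` with added `category` and `basis` columns.
#' @export
assign_category <- function(attrs, definitions) {
  if (anyDuplicated(definitions$priority)) {
    abort("Category priority ranks must be unique",
          class = "bizscape_error_config")
  }
  defs <- arrange(definitions, .data$priority)
  out <- attrs
  out$category <- "uncategorized"
  out$basis <- "none"
  unassigned <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(defs))) {
    if (!any(unassigned)) break
    def <- defs[i, ]
    hit <- unassigned & match_definition(out, def)
    if (any(hit)) {
      out$category[hit] <- def$name
      out$basis[hit] <- if_else(match_sic_patterns(out$sic[hit],
                                                   def$sic[[1]]),
                                "sic", "name")
      unassigned <- unassigned & !hit
    }
  }
  out
}

# ---- multi-year SIC resolution ----------------------------------------

#' Modal SIC across reported years
#'
#' Finds the most frequently reported primary SIC over the years a
#' business reported one, with its share of SIC-reporting years. When the
#' modal share reaches the majority threshold (at least 75 % by default —
#' the threshold is inclusive, 3 of 4 years qualifies) the modal code is
#' returned; below it, `sic` is `NA` and callers fall back to the most
#' recent code. Ties at the mode resolve toward the most recently
#' reported of the tied codes.
#'
#' @param sic Character vector of reported SICs (`NA` allowed, ignored).
#' @param year Parallel vector of reporting years (used for tie-breaks).
#' @param threshold Majority threshold on the share of reporting years.
#' @return A list with `sic` (`NA_character_` when no majority) and
#'   `fraction` (the modal share).
#' @export
majority_sic <- function(sic, year, threshold = 0.75) {
  keep <- !is.na(sic)
  if (!any(keep)) {
    abort("majority_sic: no reported SIC", class = "bizscape_error_input")
  }
  sic <- sic[keep]; year <- year[keep]
  tab <- tibble(sic = sic, year = year) |>
    group_by(.data$sic) |>
    summarise(n = n(), last = max(.data$year), .groups = "drop") |>
    arrange(dplyr::desc(.data$n), dplyr::desc(.data$last))
  frac <- tab$n[1] / sum(tab$n)
  list(sic = if (frac >= threshold) tab$sic[1] else NA_character_,
       fraction = frac)
}

#' Resolve a single SIC for a business across all years
#'
#' The majority code when one code was reported at least 75 % of the
#' reporting years; otherwise the most recently reported code (recent
#' codes tend to be more specific and more likely corrected).
#'
#' @inheritParams majority_sic
#' @return List with `sic`, `basis` (`"majority"`, `"most_recent"` or
#'   `"no_sic"`), and `fraction` (modal share, `NA` when no SIC at all).
#' @export
resolve_overall_sic <- function(sic, year, threshold = 0.75) {
  keep <- !is.na(sic)
  if (!any(keep)) {
    return(list(sic = NA_character_, basis = "no_sic", fraction = NA_real_))
  }
  m <- majority_sic(sic, year, threshold)
  if (!is.na(m$sic)) {
    list(sic = m$sic, basis = "majority", fraction = m$fraction)
  } else {
    list(sic = sic[keep][which.max(year[keep])], basis = "most_recent",
         fraction = m$fraction)
  }
}

# Vectorised overall-SIC resolution for a whole years table.
resolve_overall_sic_all <- function(years, threshold = 0.75) {
  rep_years <- years |> filter(!is.na(.data$sic))
  tab <- rep_years |>
    group_by(.data$duns_id, .data$sic) |>
    summarise(n = n(), last = max(.data$year), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$n), dplyr::desc(.data$last),
            .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()
  recent <- rep_years |>
    group_by(.data$duns_id) |>
    slice_max(.data$year, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("duns_id", recent_sic = "sic")
  all_ids <- distinct(years, .data$duns_id)
  all_ids |>
    left_join(tab, by = "duns_id") |>
    left_join(recent, by = "duns_id") |>
    mutate(sic_basis = dplyr::case_when(
             is.na(.data$sic) ~ "no_sic",
             .data$fraction >= threshold ~ "majority",
             TRUE ~ "most_recent"),
           sic = dplyr::case_when(
             .data$sic_basis == "majority" ~ .data$sic,
             .data$sic_basis == "most_recent" ~ .data$recent_sic,
             TRUE ~ NA_character_)) |>
    select("duns_id", "sic", "sic_basis", majority_fraction = "fraction")
}

most_recent_attrs <- function(years, strict_estimated = FALSE) {
  y <- years
  if (strict_estimated) {
    y <- y |> mutate(sales = if_else(.data$estimated, NA_real_, .data$sales),
                     employees = if_else(.data$estimated, NA_integer_,
                                         .data$employees))
  }
  pick_latest <- function(value_col) {
    y |>
      filter(!is.na(.data[[value_col]])) |>
      group_by(.data$duns_id) |>
      slice_max(.data$year, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select("duns_id", all_of(value_col))
  }
  distinct(y, .data$duns_id) |>
    left_join(pick_latest("sales"), by = "duns_id") |>
    left_join(pick_latest("employees"), by = "duns_id")
}

#' Categorize each business once across all years (overall mode)
#'
#' Resolves one SIC per business (majority rule with most-recent
#' fallback), pairs it with the most recently reported name, sales and
#' employee count, and applies [assign_category()]. This is the "single
#' classification across all years" mode.
#'
#' @param bundle A `nets_registry`.
#' @param definitions From [load_category_definitions()].
#' @param threshold Majority threshold (default 0.75, inclusive).
#' @param strict_estimated Treat upstream-imputed sales/employee values
#'   as missing (default uses them as-is).
#' @return Tibble: `duns_id`, `sic`, `sic_basis`, `majority_fraction`,
#'   `category`, `basis`.
#' @export
categorize_overall <- function(bundle, definitions, threshold = 0.75,
                               strict_estimated = FALSE) {
  attrs <- resolve_overall_sic_all(bundle$years, threshold) |>
    left_join(bundle$establishments, by = "duns_id") |>
    left_join(most_recent_attrs(bundle$years, strict_estimated),
              by = "duns_id")
  assign_category(attrs, definitions) |>
    select("duns_id", "sic", "sic_basis", "majority_fraction",
           "category", "basis")
}

#' Categorize each business-year separately (yearly mode)
#'
#' Applies the category rules with the SIC, sales and employee count
#' specific to each year (names in the registry are the most recent on
#' file and are used for all years). A business can change category from
#' year to year in this mode.
#'
#' @param bundle A `nets_registry`.
#' @param definitions From [load_category_definitions()].
#' @param years Optional integer vector restricting which calendar years
#'   to classify; an error if none of them is an active year.
#' @param strict_estimated See [categorize_overall()].
#' @return Tibble: `duns_id`, `year`, `sic`, `category`, `basis`.
#' @export
categorize_yearly <- function(bundle, definitions, years = NULL,
                              strict_estimated = FALSE) {
  y <- bundle$years
  if (!is.null(years)) {
    y <- y |> filter(.data$year %in% years)
    if (nrow(y) == 0L) {
      abort("Requested year(s) outside every business's activity",
            class = "bizscape_error_input")
    }
  }
  if (strict_estimated) {
    y <- y |> mutate(sales = if_else(.data$estimated, NA_real_, .data$sales),
                     employees = if_else(.data$estimated, NA_integer_,
                                         .data$employees))
  }
  attrs <- y |> left_join(bundle$establishments, by = "duns_id")
  assign_category(attrs, definitions) |>
    select("duns_id", "year", "sic", "category", "basis")
}

# ---- MET banding and SIC review sampling -------------------------------

#' Band a physical-activity MET value
#'
#' Venues are banded by the metabolic equivalent (MET) of the activity
#' generally offered: light/moderate for 1.6-5.9 METs, vigorous for 6
#' METs and above. Values below 1.6 are sedentary and outside the
#' scheme (an error).
#'
#' @param met_value Numeric vector of MET values (each >= 1.6).
#' @return Character vector, `"light_moderate"` or `"vigorous"`.
#' @export
met_band <- function(met_value) {
  if (any(is.na(met_value)) || any(met_value < 1.6)) {
    abort("MET values below 1.6 are sedentary and outside the banding scheme",
          class = "bizscape_error_input")
  }
  if_else(met_value < 6, "light_moderate", "vigorous")
}

#' Review sample size for a candidate SIC
#'
#' How many establishments reporting a candidate SIC in the reference
#' year get manually reviewed before the SIC is admitted to a category
#' definition: all of them when fewer than 50 exist, a 20 % random sample
#' (rounded up) for frequencies of 50-250, and a flat 50 above 250.
#'
#' @param frequency Nonnegative integer vector of SIC frequencies in the
#'   reference year.
#' @return Integer vector of sample sizes.
#' @export
review_sample_size <- function(frequency) {
  if (any(is.na(frequency)) || any(frequency < 0)) {
    abort("SIC frequencies must be nonnegative",
          class = "bizscape_error_input")
  }
  out <- ifelse(frequency < 50, frequency,
                ifelse(frequency <= 250, ceiling(0.20 * frequency), 50))
  as.integer(out)
}

#' Draw a seeded review sample for one candidate SIC
#'
#' Draws a uniform random sample of establishments (size from
#' [review_sample_size()]) and returns a review worksheet carrying the
#' name fields plus an empty `relevant` column for the reviewer to mark.
#'
#' @param businesses Tibble of establishments reporting the SIC
#'   (`duns_id`, `company_name`, `trade_name`, ...).
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return The worksheet tibble (sampled rows, `relevant` = `NA`).
#' @export
draw_review_sample <- function(businesses, seed) {
  n <- nrow(businesses)
  size <- review_sample_size(n)
  idx <- with_seed(seed, sample.int(n, size))
  businesses[sort(idx), , drop = FALSE] |>
    mutate(relevant = NA)
}

#' Decide SIC inclusion from a marked review worksheet
#'
#' An SIC enters a category definition when at least half of the
#' reviewed sample is relevant to the category; exactly 50 % includes.
#'
#' @param worksheet Worksheet from [draw_review_sample()] with the
#'   `relevant` column marked `TRUE`/`FALSE`.
#' @return `"include"` or `"exclude"`.
#' @export
evaluate_review <- function(worksheet) {
  rel <- worksheet$relevant
  if (length(rel) == 0L || anyNA(rel)) {
    abort("Review worksheet must have every 'relevant' cell marked",
          class = "bizscape_error_input")
  }
  if (mean(rel) >= 0.5) "include" else "exclude"
}
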