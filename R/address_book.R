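the_suffix_cache <- new.env(parent = emptyenv())

#' Street-suffix expansion table
#'
#' The abbreviation table used by [normalize_address()] (ST to STREET,
#' AVE to AVENUE, ...). Shipped as editable data under
#' `inst/extdata/street_suffixes.csv` rather than hard-coded, since
#' suffix dialects vary by region; pass a custom path to override.
#'
#' @param path Optional path to a two-column CSV (`abbrev`, `full`).
#' @return Tibble with columns `abbrev` and `full`, both upper case.
#' @export
street_suffix_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_suffix_cache$default)) return(the_suffix_cache$default)
    path <- system.file("extdata", "street_suffixes.csv",
                        package = "bizscape")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(abbrev = toupper(.data$abbrev), full = toupper(.data$full))
  if (is.null(the_suffix_cache$default) &&
      identical(path, system.file("extdata", "street_suffixes.csv",
                                  package = "bizscape"))) {
    the_suffix_cache$default <- tab
  }
  tab
}

#' Canonicalise an address string
#'
#' Addresses for the same location are recorded with deviations in the
#' character string across files and years; comparison therefore happens
#' on a canonical form. Normalisation upper-cases, strips punctuation,
#' collapses runs of whitespace, and expands street-suffix abbreviations
#' token-wise through [street_suffix_table()]. The function is
#' idempotent: a canonical string maps to itself.
#'
#' @param x Character vector of address strings (`NA` and `""` pass
#'   through).
#' @param suffixes Suffix table, see [street_suffix_table()].
#' @return Character vector of canonical strings.
#' @examples
#' normalize_address(c("10 Main St.", "10  MAIN STREET"))
#' @export
normalize_address <- function(x, suffixes = street_suffix_table()) {
  out <- toupper(x)
  out <- stringr::str_replace_all(out, "[^A-Z0-9]+", " ")
  out <- stringr::str_squish(out)
  map <- setNames(suffixes$full, suffixes$abbrev)
  expand <- function(s) {
    if (is.na(s) || s == "") return(s)
    tok <- strsplit(s, " ", fixed = TRUE)[[1]]
    hit <- tok %in% names(map)
    tok[hit] <- map[tok[hit]]
    paste(tok, collapse = " ")
  }
  vapply(out, expand, character(1), USE.NAMES = FALSE)
}

#' Normalise a company or trade name
#'
#' Upper-case, punctuation stripped, whitespace collapsed — the form on
#' which category name patterns are matched. No suffix expansion.
#'
#' @param x Character vector.
#' @return Character vector.
#' @export
normalize_name <- function(x) {
  stringr::str_squish(stringr::str_replace_all(toupper(x), "[^A-Z0-9]+", " "))
}

#' Significant-move predicate
#'
#' A relocation counts as a significant move only when **both** the street
#' address and the five-digit zip code change between years; a renumbering
#' within the same zip, or a zip realignment of an unchanged street
#' address, does not. Street addresses are compared on their normalised
#' form.
#'
#' @param origin,dest Data frames (or lists) with elements `line` and
#'   `zip5`; vectorised row-wise.
#' @param suffixes Suffix table for normalisation.
#' @return Logical vector.
#' @export
is_significant_move <- function(origin, dest,
                                suffixes = street_suffix_table()) {
  o_zip <- origin$zip5
  d_zip <- dest$zip5
  if (anyNA(o_zip) || anyNA(d_zip) ||
      !all(is_valid_zip5(o_zip)) || !all(is_valid_zip5(d_zip))) {
    abort("Cannot evaluate significant-move predicate without valid 5-digit zips",
          class = "bizscape_error_input")
  }
  street_changed <- normalize_address(origin$line, suffixes) !=
    normalize_address(dest$line, suffixes)
  zip_changed <- o_zip != d_zip
  street_changed & zip_changed
}

#' Build the comprehensive address file
#'
#' Expands a registry into one row per establishment location-role: every
#' business carries a `first` and a `most_recent` role, and a business
#' with k significant moves additionally carries `origin` and
#' `destination` roles for each move — 2 + 2k roles in total, describing
#' at most k + 1 distinct locations.
#'
#' Internal consistency is checked on normalised strings: for a
#' non-mover, first and most recent addresses are expected to be
#' equivalent; for a mover, the first address should match the origin of
#' move 1, consecutive moves should chain (destination k = origin k+1),
#' and the final destination should match the most recent address.
#' Discrepancies are recorded in the `note` column (and summarised in the
#' `"discrepancies"` attribute) but never dropped; where versions of the
#' same location disagree, the destination / most-recent string is the
#' one the year-assignment uses.
#'
#' @param bundle A `nets_registry`.
#' @param suffixes Suffix table for normalisation.
#' @return Tibble with columns `duns_id`, `role`, `move_index`, `line`,
#'   `alt`, `zip5`, `normalized`, `note`.
#' @export
build_address_book <- function(bundle, suffixes = street_suffix_table()) {
  est <- bundle$establishments
  movers <- unique(bundle$moves$duns_id)

  recent <- bundle$recent_address
  missing_recent <- setdiff(est$duns_id, recent$duns_id)
  if (length(missing_recent)) {
    abort(paste0("No most-recent address for: ",
                 paste(head(missing_recent, 5), collapse = ", ")),
          class = "bizscape_error_address")
  }
  first <- bundle$first_address
  missing_first <- setdiff(est$duns_id, first$duns_id)
  first_fallback <- recent |>
    filter(.data$duns_id %in% missing_first)
  first <- bind_rows(first, first_fallback)

  rows <- bind_rows(
    first |> mutate(role = "first", move_index = NA_integer_,
                    note = if_else(.data$duns_id %in% missing_first,
                                   "first address missing; most-recent used",
                                   NA_character_)),
    recent |> mutate(role = "most_recent", move_index = NA_integer_,
                     note = NA_character_),
    bundle$moves |>
      select("duns_id", "move_index",
             line = "origin_line", alt = "origin_alt",
             zip5 = "origin_zip5") |>
      mutate(role = "origin", note = NA_character_),
    bundle$moves |>
      select("duns_id", "move_index",
             line = "dest_line", alt = "dest_alt", zip5 = "dest_zip5") |>
      mutate(role = "destination", note = NA_character_)
  ) |>
    mutate(normalized = normalize_address(.data$line, suffixes)) |>
    select("duns_id", "role", "move_index", "line", "alt", "zip5",
           "normalized", "note") |>
    arrange(.data$duns_id, .data$role, .data$move_index)

  key <- function(df) paste(df$normalized, df$zip5)
  wide <- rows |>
    mutate(k = paste0(.data$role,
                      if_else(is.na(.data$move_index), "",
                              paste0("_", .data$move_index))))
  lookup <- setNames(key(wide), paste(wide$duns_id, wide$k))
  get1 <- function(duns, k) unname(lookup[paste(duns, k)])

  disc <- list()
  non_movers <- setdiff(est$duns_id, movers)
  nm_bad <- non_movers[get1(non_movers, "first") !=
                         get1(non_movers, "most_recent")]
  if (length(nm_bad)) {
    disc$non_mover <- tibble(duns_id = nm_bad,
                             check = "first vs most_recent")
  }
  if (length(movers)) {
    mv <- bundle$moves |>
      group_by(.data$duns_id) |>
      summarise(kmax = max(.data$move_index), .groups = "drop")
    f_bad <- mv$duns_id[get1(mv$duns_id, "first") !=
                          get1(mv$duns_id, "origin_1")]
    l_bad <- mv$duns_id[get1(mv$duns_id, paste0("destination_", mv$kmax)) !=
                          get1(mv$duns_id, "most_recent")]
    chain <- bundle$moves |>
      filter(.data$move_index > 1) |>
      mutate(prev = get1(.data$duns_id,
                         paste0("destination_", .data$move_index - 1)),
             this = get1(.data$duns_id, paste0("origin_", .data$move_index)))
    c_bad <- unique(chain$duns_id[chain$prev != chain$this])
    if (length(f_bad)) disc$first <- tibble(duns_id = f_bad,
                                            check = "first vs origin 1")
    if (length(l_bad)) disc$last <- tibble(duns_id = l_bad,
                                           check = "last destination vs most_recent")
    if (length(c_bad)) disc$chain <- tibble(duns_id = c_bad,
                                            check = "destination k vs origin k+1")
  }
  disc <- bind_rows(disc)
  if (nrow(disc)) {
    inform(paste0("build_address_book: ", nrow(disc),
                  " expected-equivalence discrepancies (see attr 'discrepancies')"))
  }
  out <- rows
  attr(out, "discrepancies") <- disc
  out
}

#' Assign one location-role to every business-year
#'
#' The first-address role is in force from a business's first active year
#' until its first significant move; thereafter the destination of move k
#' is in force from the move year itself (by default) until the year
#' before move k+1, with the last destination carrying through the final
#' active year. Registry snapshots are taken annually, so under the
#' default convention a business observed in its move year is placed at
#' the destination; `boundary = "year_after"` keeps it at the origin
#' through the move year instead.
#'
#' @param book Address book from [build_address_book()].
#' @param moves The registry's moves tibble.
#' @param years The registry's years tibble (defines active
#'   business-years).
#' @param boundary `"move_year"` (default) or `"year_after"`.
#' @return Tibble `duns_id`, `year`, `role`, `move_index`, plus the
#'   address columns of the role in force; one row per active
#'   business-year.
#' @export
assign_yearly_locations <- function(book, moves, years,
                                    boundary = c("move_year", "year_after")) {
  boundary <- match.arg(boundary)
  if (nrow(moves)) {
    ooo <- moves |>
      arrange(.data$duns_id, .data$move_index) |>
      group_by(.data$duns_id) |>
      summarise(ok = !is.unsorted(.data$move_year, strictly = FALSE),
                .groups = "drop")
    if (!all(ooo$ok)) {
      abort(paste0("Moves out of chronological order for: ",
                   paste(head(ooo$duns_id[!ooo$ok], 5), collapse = ", ")),
            class = "bizscape_error_moves")
    }
  }
  off <- if (boundary == "move_year") 0L else 1L
  yl <- years |> select("duns_id", "year")
  k <- yl |>
    inner_join(moves |> select("duns_id", "move_index", "move_year"),
               by = "duns_id", relationship = "many-to-many") |>
    filter(.data$move_year + off <= .data$year) |>
    group_by(.data$duns_id, .data$year) |>
    summarise(move_index = max(.data$move_index), .groups = "drop")
  out <- yl |>
    left_join(k, by = c("duns_id", "year")) |>
    mutate(role = if_else(is.na(.data$move_index), "first", "destination"))
  out |>
    left_join(book |>
                select("duns_id", "role", "move_index", "line", "alt",
                       "zip5", "normalized"),
              by = c("duns_id", "role", "move_index")) |>
    arrange(.data$duns_id, .data$year)
}
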