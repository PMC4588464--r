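#' Construct a registry bundle from tibbles
#'
#' The in-memory data model for a NETS-style longitudinal establishment
#' registry: a set of linked tibbles keyed by the nine-digit DUNS
#' establishment identifier. Most users will obtain one from
#' [read_registry()] or [generate_registry()] rather than build it by hand.
#'
#' @param establishments Tibble with `duns_id`, `company_name`,
#'   `trade_name` (may be `NA`); one row per establishment.
#' @param years Tibble with `duns_id`, `year`, `sic` (8-digit string or
#'   `NA`), `sales`, `employees`, `estimated`; one row per active
#'   business-year. A year with a reported SIC must be an active year.
#' @param moves Tibble of significant moves: `duns_id`, `move_index`
#'   (1-based, consecutive per business), `move_year`, and origin /
#'   destination address fields (`origin_line`, `origin_alt`,
#'   `origin_zip5`, `dest_line`, `dest_alt`, `dest_zip5`).
#' @param first_address,recent_address Tibbles with `duns_id`, `line`,
#'   `alt`, `zip5`.
#' @param vendor_geocodes Tibble of delivery-supplied coordinates:
#'   `duns_id`, `role` (`first`, `most_recent`, `origin`, `destination`),
#'   `move_index` (`NA` except for move roles), `source`, `lat`, `lon`,
#'   `precision` (see [precision_levels()]).
#' @param issues Tibble of row-level problems recorded while reading;
#'   empty for programmatically built bundles.
#' @return An object of class `nets_registry`.
#' @export
registry_bundle <- function(establishments, years,
                            moves = empty_moves(),
                            first_address = empty_address(),
                            recent_address = empty_address(),
                            vendor_geocodes = empty_geocodes(),
                            issues = empty_issues()) {
  bundle <- structure(
    list(establishments = as_tibble(establishments),
         years = as_tibble(years),
         moves = as_tibble(moves),
         first_address = as_tibble(first_address),
         recent_address = as_tibble(recent_address),
         vendor_geocodes = as_tibble(vendor_geocodes),
         issues = as_tibble(issues)),
    class = "nets_registry")
  validate_registry(bundle)
}

empty_moves <- function() {
  tibble(duns_id = character(), move_index = integer(),
         move_year = integer(),
         origin_line = character(), origin_alt = character(),
         origin_zip5 = character(),
         dest_line = character(), dest_alt = character(),
         dest_zip5 = character())
}

empty_address <- function() {
  tibble(duns_id = character(), line = character(), alt = character(),
         zip5 = character())
}

empty_geocodes <- function() {
  tibble(duns_id = character(), role = character(), move_index = integer(),
         source = character(), lat = double(), lon = double(),
         precision = character())
}

empty_issues <- function() {
  tibble(file = character(), row = integer(), duns_id = character(),
         problem = character())
}

#' Validate registry invariants
#'
#' Checks identifier format and uniqueness, referential integrity of the
#' auxiliary tables, consecutive move indices, and that SIC-reporting
#' years are active years. Called by [registry_bundle()]; exposed for
#' re-checking a bundle after manual edits.
#'
#' @param bundle A `nets_registry`.
#' @return The bundle, invisibly unchanged, or an error.
#' @export
validate_registry <- function(bundle) {
  est <- bundle$establishments
  if (anyDuplicated(est$duns_id)) {
    dup <- unique(est$duns_id[duplicated(est$duns_id)])
    abort(paste0("Duplicate duns_id in establishment table: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "bizscape_error_duplicate_duns")
  }
  bad <- est$duns_id[!is_valid_duns(est$duns_id)]
  if (length(bad)) {
    abort(paste0("Malformed duns_id (must be 9 digits): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "bizscape_error_duns")
  }
  if (nrow(bundle$years) == 0 && nrow(est) > 0) {
    abort("Every establishment needs at least one active year",
          class = "bizscape_error_invariant")
  }
  known <- est$duns_id
  for (tab in c("years", "moves", "first_address", "recent_address",
                "vendor_geocodes")) {
    unknown <- setdiff(bundle[[tab]]$duns_id, known)
    if (length(unknown)) {
      abort(paste0("Table '", tab, "' references unknown duns_id: ",
                   paste(head(unknown, 5), collapse = ", ")),
            class = "bizscape_error_integrity")
    }
  }
  inactive <- is.na(bundle$years$sic) & is.na(bundle$years$sales) &
    is.na(bundle$years$employees)
  if (any(inactive)) {
    abort("years table contains rows with no reported values",
          class = "bizscape_error_invariant")
  }
  no_year <- setdiff(known, unique(bundle$years$duns_id))
  if (length(no_year)) {
    abort(paste0("Establishments with no active years: ",
                 paste(head(no_year, 5), collapse = ", ")),
          class = "bizscape_error_invariant")
  }
  mv <- bundle$moves
  if (nrow(mv)) {
    ok <- mv |>
      group_by(.data$duns_id) |>
      summarise(consec = identical(sort(.data$move_index),
                                   seq_along(.data$move_index)),
                .groups = "drop")
    if (!all(ok$consec)) {
      abort(paste0("Non-consecutive move_index for: ",
                   paste(head(ok$duns_id[!ok$consec], 5), collapse = ", ")),
            class = "bizscape_error_moves")
    }
  }
  invisible(bundle)
}

#' @export
print.nets_registry <- function(x, ...) {
  yr <- range(x$years$year)
  cat("<nets_registry>\n")
  cat("  establishments:", nrow(x$establishments), "\n")
  cat("  business-years:", nrow(x$years),
      sprintf("(%d-%d)\n", yr[1], yr[2]))
  cat("  significant moves:", nrow(x$moves),
      sprintf("(%d movers)\n", dplyr::n_distinct(x$moves$duns_id)))
  cat("  vendor geocodes:", nrow(x$vendor_geocodes), "\n")
  if (nrow(x$issues)) cat("  read issues:", nrow(x$issues), "\n")
  invisible(x)
}

# ---- file recognition --------------------------------------------------

yearcol_rx <- "^(sic|sales|emp|est)_([0-9]{4})$"

#' Recognise a NETS-dialect file by its column signature
#'
#' File names vary across registry deliveries, so files are identified by
#' required-column signatures, never by name: the wide establishment file
#' carries per-year `sic_YYYY`/`emp_YYYY` columns, the moves file carries
#' `moveindex` and destination address columns, geocode files carry
#' latitude/longitude/precision, and the first-address file is the
#' remaining address-bearing layout.
#'
#' @param cols Character vector of column names.
#' @return One of `"establishments"`, `"moves"`, `"first_address"`,
#'   `"geocodes"`, or an error for an unrecognised signature.
#' @export
recognize_nets_file <- function(cols) {
  cols <- tolower(cols)
  has <- function(...) all(c(...) %in% cols)
  if ("dunsnumber" %in% cols && any(grepl(yearcol_rx, cols))) {
    return("establishments")
  }
  if (has("dunsnumber", "moveindex", "destaddress", "destzip")) {
    return("moves")
  }
  if (has("dunsnumber", "latitude", "longitude", "precision")) {
    return("geocodes")
  }
  if (has("dunsnumber", "address", "zipcode")) {
    return("first_address")
  }
  abort(paste0("Unrecognised file signature: ", paste(cols, collapse = ", ")),
        class = "bizscape_error_dialect")
}

read_nets_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = c("", "NA"))
  names(df) <- tolower(names(df))
  df
}

#' Read a NETS-dialect registry from tab-delimited files
#'
#' Reads the wide establishment file (one row per establishment, yearly
#' SIC/sales/employee columns, most recent name and address), the long
#' significant-moves file, the first-address file, and any number of
#' per-source geocode files, then merges them into a single
#' [registry_bundle()] keyed by DUNS number. Files are matched to roles by
#' column signature ([recognize_nets_file()]); an explicit `dialect`
#' override map can pin a path to a role when a delivery uses ambiguous
#' layouts.
#'
#' Rows in auxiliary files that reference a DUNS number absent from the
#' establishment file, and rows with malformed (non nine-digit)
#' identifiers, are dropped and reported in the bundle's `issues` table
#' with their file and row number. A duplicated DUNS number in the wide
#' file is a hard error.
#'
#' @param paths Character vector of file paths (any order, any names).
#' @param dialect Optional list; `dialect$files` may be a named character
#'   vector mapping roles (`establishments`, `moves`, `first_address`,
#'   `geocodes`) to paths, bypassing recognition for those files.
#' @return A `nets_registry`.
#' @export
read_registry <- function(paths, dialect = NULL) {
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    abort(paste0("Input file(s) not found: ",
                 paste(missing_files, collapse = ", ")),
          class = "bizscape_error_io")
  }
  override <- dialect$files %||% character()
  kinds <- character(length(paths))
  tables <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    tables[[i]] <- read_nets_tsv(paths[i])
    pinned <- names(override)[match(normalizePath(paths[i]),
                                    suppressWarnings(normalizePath(override,
                                                                   mustWork = FALSE)))]
    kinds[i] <- if (length(pinned) && !is.na(pinned)) pinned
                else recognize_nets_file(names(tables[[i]]))
  }
  if (sum(kinds == "establishments") != 1L) {
    abort("Exactly one wide establishment file is required",
          class = "bizscape_error_dialect")
  }
  issues <- empty_issues()
  note <- function(file, rows, ids, problem) {
    if (length(rows) == 0) return()
    issues <<- bind_rows(issues,
                         tibble(file = basename(file), row = as.integer(rows),
                                duns_id = ids, problem = problem))
  }

  wide_path <- paths[kinds == "establishments"]
  wide <- tables[[which(kinds == "establishments")]]
  bad <- which(!is_valid_duns(wide$dunsnumber))
  note(wide_path, bad, wide$dunsnumber[bad], "malformed duns_id")
  if (length(bad)) wide <- wide[-bad, ]
  if (anyDuplicated(wide$dunsnumber)) {
    abort(paste0("Duplicate duns_id in wide establishment file: ",
                 paste(head(unique(wide$dunsnumber[duplicated(wide$dunsnumber)]), 5),
                       collapse = ", ")),
          class = "bizscape_error_duplicate_duns")
  }
  parsed <- parse_wide(wide)
  known <- parsed$establishments$duns_id

  keep_known <- function(df, file) {
    bad_id <- which(!is_valid_duns(df$dunsnumber))
    note(file, bad_id, df$dunsnumber[bad_id], "malformed duns_id")
    unknown <- which(is_valid_duns(df$dunsnumber) &
                       !(df$dunsnumber %in% known))
    note(file, unknown, df$dunsnumber[unknown], "unknown duns_id")
    drop <- union(bad_id, unknown)
    if (length(drop)) df[-drop, ] else df
  }

  moves <- empty_moves()
  for (i in which(kinds == "moves")) {
    df <- keep_known(tables[[i]], paths[i])
    moves <- bind_rows(moves, tibble(
      duns_id = df$dunsnumber,
      move_index = as.integer(df$moveindex),
      move_year = as.integer(df$moveyear),
      origin_line = df$originaddress,
      origin_alt = df$originaltaddress %||% NA_character_,
      origin_zip5 = df$originzip,
      dest_line = df$destaddress,
      dest_alt = df$destaltaddress %||% NA_character_,
      dest_zip5 = df$destzip))
  }

  first_address <- empty_address()
  for (i in which(kinds == "first_address")) {
    df <- keep_known(tables[[i]], paths[i])
    first_address <- bind_rows(first_address, tibble(
      duns_id = df$dunsnumber, line = df$address,
      alt = df$altaddress %||% NA_character_, zip5 = df$zipcode))
  }

  geocodes <- empty_geocodes()
  for (i in which(kinds == "geocodes")) {
    df <- keep_known(tables[[i]], paths[i])
    geocodes <- bind_rows(geocodes, tibble(
      duns_id = df$dunsnumber,
      role = df$role,
      move_index = as.integer(df$moveindex %||% NA_character_),
      source = df$source %||% "vendor_supplied",
      lat = as.double(df$latitude),
      lon = as.double(df$longitude),
      precision = df$precision))
  }

  if (length(issues$problem)) {
    inform(paste0("read_registry: dropped ", nrow(issues),
                  " row(s); see bundle$issues"))
  }
  registry_bundle(parsed$establishments, parsed$years, moves,
                  first_address, parsed$recent_address, geocodes, issues)
}

parse_wide <- function(wide) {
  yc <- grep(yearcol_rx, names(wide), value = TRUE)
  establishments <- tibble(duns_id = wide$dunsnumber,
                           company_name = wide$company,
                           trade_name = wide$tradename %||% NA_character_)
  recent_address <- tibble(duns_id = wide$dunsnumber,
                           line = wide$address,
                           alt = wide$altaddress %||% NA_character_,
                           zip5 = wide$zipcode)
  long <- wide |>
    select("dunsnumber", all_of(yc)) |>
    tidyr::pivot_longer(all_of(yc),
                        names_to = c("field", "year"), names_sep = "_",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = "field", values_from = "value")
  for (f in c("sic", "sales", "emp", "est")) {
    if (!f %in% names(long)) long[[f]] <- NA_character_
  }
  years <- long |>
    filter(!(is.na(.data$sic) & is.na(.data$sales) & is.na(.data$emp))) |>
    mutate(year = as.integer(.data$year)) |>
    transmute_years()
  list(establishments = establishments, years = years,
       recent_address = recent_address)
}

transmute_years <- function(long) {
  tibble(duns_id = long$dunsnumber,
         year = long$year,
         sic = long$sic,
         sales = as.double(long$sales),
         employees = as.integer(long$emp),
         estimated = !is.na(long$est) & long$est %in% c("1", "TRUE", "true"))
}

# ---- writing -----------------------------------------------------------

check_no_tabs <- function(df, file) {
  chr <- vapply(df, is.character, logical(1))
  if (any(vapply(df[chr], function(col) any(grepl("\t", col), na.rm = TRUE),
                 logical(1)))) {
    abort(paste0("Embedded tab character in field values for ", file),
          class = "bizscape_error_io")
  }
  invisible(df)
}

#' Write a registry bundle as NETS-dialect tab-delimited files
#'
#' Writes `establishments.tsv` (wide), `moves.tsv`, `first_address.tsv`
#' and one `geocodes_<source>.tsv` per geocode source, with a
#' deterministic column order. The output round-trips losslessly through
#' [read_registry()]. Tab is the only separator; embedded tabs in field
#' values are rejected.
#'
#' @param bundle A `nets_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_registry <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("Cannot create output directory: ", dir),
          class = "bizscape_error_io")
  }
  yrs <- sort(unique(bundle$years$year))
  wide <- bundle$years |>
    mutate(est = if_else(.data$estimated, "1", NA_character_),
           sic = .data$sic,
           sales = as.character(.data$sales),
           emp = as.character(.data$employees)) |>
    select("duns_id", "year", "sic", "sales", "emp", "est") |>
    tidyr::pivot_longer(c("sic", "sales", "emp", "est"),
                        names_to = "field", values_to = "value") |>
    mutate(col = paste0(.data$field, "_", .data$year)) |>
    select("duns_id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  ordered_cols <- as.vector(t(outer(c("sic", "sales", "emp", "est"), yrs,
                                    paste, sep = "_")))
  ordered_cols <- intersect(ordered_cols, names(wide))
  wide <- bundle$establishments |>
    left_join(bundle$recent_address, by = "duns_id") |>
    left_join(wide, by = "duns_id") |>
    select(dunsnumber = "duns_id", company = "company_name",
           tradename = "trade_name", address = "line", altaddress = "alt",
           zipcode = "zip5", all_of(ordered_cols))

  paths <- character()
  wr <- function(df, file) {
    p <- file.path(dir, file)
    check_no_tabs(df, file)
    readr::write_tsv(df, p, na = "", progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(wide, "establishments.tsv")
  wr(bundle$moves |>
       select(dunsnumber = "duns_id", moveindex = "move_index",
              moveyear = "move_year", originaddress = "origin_line",
              originaltaddress = "origin_alt", originzip = "origin_zip5",
              destaddress = "dest_line", destaltaddress = "dest_alt",
              destzip = "dest_zip5"),
     "moves.tsv")
  wr(bundle$first_address |>
       select(dunsnumber = "duns_id", address = "line", altaddress = "alt",
              zipcode = "zip5"),
     "first_address.tsv")
  gc_split <- split(bundle$vendor_geocodes, bundle$vendor_geocodes$source)
  for (src in names(gc_split)) {
    wr(gc_split[[src]] |>
         select(dunsnumber = "duns_id", role = "role",
                moveindex = "move_index", source = "source",
                latitude = "lat", longitude = "lon",
                precision = "precision"),
       paste0("geocodes_", src, ".tsv"))
  }
  invisible(paths)
}

#' Write any stage output table to CSV with a provenance header
#'
#' Stage outputs (address book, location assignments, category
#' assignments, count tables, trends) are plain tibbles; this writes them
#' as CSV preceded by `#`-prefixed provenance comment lines recording the
#' generating seed, so a written artefact carries its reproducibility
#' information. Read back with [read_stage_csv()].
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param seed Optional integer seed recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_stage_csv <- function(x, path, seed = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  header <- c(sprintf("# bizscape %s", as.character(utils::packageVersion("bizscape"))),
              if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
  body <- strsplit(readr::format_csv(x, na = ""), "\n", fixed = TRUE)[[1]]
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a stage CSV written by [write_stage_csv()]
#'
#' @param path File path.
#' @return A tibble; the provenance header is attached as attribute
#'   `"provenance"`.
#' @export
read_stage_csv <- function(path) {
  hdr <- character()
  con <- file(path, open = "rt")
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "provenance") <- hdr
  out
}
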