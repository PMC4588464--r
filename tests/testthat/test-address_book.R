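test_that("address normalisation canonicalises spacing, case and suffixes", {
  expect_equal(normalize_address("10 Main St."),
               normalize_address("10  MAIN STREET"))
  expect_equal(normalize_address("10 Main St."), "10 MAIN STREET")
  expect_equal(normalize_address(""), "")
  expect_true(is.na(normalize_address(NA_character_)))
})

test_that("normalisation is idempotent and matches the suffix table", {
  tab <- utils::read.csv(system.file("extdata", "street_suffixes.csv",
                                     package = "bizscape"))
  raw <- paste0("12 OAK ", tolower(tab$abbrev), ".")
  expected <- paste("12 OAK", toupper(tab$full))
  got <- normalize_address(raw)
  expect_equal(got, expected)
  expect_equal(normalize_address(got), got)
})

test_that("a significant move needs both street and zip to change", {
  ad <- function(line, zip) data.frame(line = line, zip5 = zip)
  # same street, different zip: not significant
  expect_false(is_significant_move(ad("10 MAIN ST", "10001"),
                                   ad("10 MAIN STREET", "10002")))
  # different street, same zip: not significant
  expect_false(is_significant_move(ad("10 MAIN ST", "10001"),
                                   ad("22 OAK AVE", "10001")))
  # both change: significant
  expect_true(is_significant_move(ad("10 MAIN ST", "10001"),
                                  ad("22 OAK AVE", "10002")))
  # identical addresses: not a move
  expect_false(is_significant_move(ad("10 MAIN ST", "10001"),
                                   ad("10 MAIN ST", "10001")))
  # unusable zip is an error, not a silent FALSE
  expect_error(is_significant_move(ad("10 MAIN ST", NA),
                                   ad("22 OAK AVE", "10002")),
               class = "bizscape_error_input")
})

test_that("address book has 2 + 2k roles and at most k + 1 locations", {
  b <- toy_bundle()
  book <- suppressMessages(build_address_book(b))
  roles <- dplyr::count(book, duns_id)
  # non-movers: first + most_recent; the 1-mover: + origin/destination
  expect_equal(roles$n[roles$duns_id == "111111111"], 2)
  expect_equal(roles$n[roles$duns_id == "333333333"], 4)
  locs <- book |>
    dplyr::distinct(duns_id, normalized, zip5) |>
    dplyr::count(duns_id)
  expect_equal(locs$n[locs$duns_id == "111111111"], 1)
  expect_equal(locs$n[locs$duns_id == "333333333"], 2)

  g <- generate_registry(synth_params(n_establishments = 500, seed = 17))
  book_s <- suppressMessages(build_address_book(g$bundle))
  k <- g$bundle$moves |> dplyr::count(duns_id, name = "k")
  sizes <- book_s |>
    dplyr::count(duns_id) |>
    dplyr::left_join(k, by = "duns_id") |>
    dplyr::mutate(k = dplyr::coalesce(k, 0L))
  expect_true(all(sizes$n == 2 + 2 * sizes$k))
  n_locs <- book_s |>
    dplyr::distinct(duns_id, normalized, zip5) |>
    dplyr::count(duns_id) |>
    dplyr::left_join(k, by = "duns_id") |>
    dplyr::mutate(k = dplyr::coalesce(k, 0L))
  expect_true(all(n_locs$n <= n_locs$k + 1))
})

test_that("book location count equals the truth table's distinct sites", {
  g <- generate_registry(synth_params(n_establishments = 1000, seed = 19))
  book <- suppressMessages(build_address_book(g$bundle))
  got <- book |>
    dplyr::distinct(duns_id, normalized, zip5) |>
    dplyr::count(duns_id, name = "book")
  want <- g$truth$locations |>
    dplyr::distinct(duns_id, x, y) |>
    dplyr::count(duns_id, name = "truth")
  cmp <- dplyr::inner_join(got, want, by = "duns_id")
  expect_equal(nrow(cmp), 1000)
  expect_equal(cmp$book, cmp$truth)
})

test_that("expected-equivalence discrepancies are flagged, not dropped", {
  b <- toy_bundle()
  fa <- b$first_address
  fa$line[fa$duns_id == "111111111"] <- "999 TOTALLY DIFFERENT RD"
  fa$zip5[fa$duns_id == "111111111"] <- "10099"
  b2 <- registry_bundle(b$establishments, b$years, b$moves, fa,
                        b$recent_address, b$vendor_geocodes)
  expect_message(book <- build_address_book(b2), "discrepanc")
  disc <- attr(book, "discrepancies")
  expect_true("111111111" %in% disc$duns_id)
  expect_equal(sum(book$duns_id == "111111111"), 2)
})

test_that("yearly location roles are piecewise constant at move years", {
  b <- toy_bundle()
  book <- suppressMessages(build_address_book(b))
  ym <- assign_yearly_locations(book, b$moves, b$years)
  # non-mover: same role every year
  expect_equal(unique(ym$role[ym$duns_id == "111111111"]), "first")
  # the 1991 mover: first for 1990, destination from the move year on
  m <- ym[ym$duns_id == "333333333", ]
  expect_equal(m$role[m$year == 1990], "first")
  expect_equal(m$role[m$year %in% 1991:1992], c("destination", "destination"))
  expect_equal(m$zip5[m$year == 1990], "10001")
  expect_equal(m$zip5[m$year == 1992], "10011")
  # alternate boundary convention: destination from the year after
  ym2 <- assign_yearly_locations(book, b$moves, b$years,
                                 boundary = "year_after")
  m2 <- ym2[ym2$duns_id == "333333333", ]
  expect_equal(m2$role[m2$year == 1991], "first")
  expect_equal(m2$role[m2$year == 1992], "destination")
})

test_that("every active business-year receives exactly one location", {
  g <- generate_registry(synth_params(n_establishments = 400, seed = 23))
  book <- suppressMessages(build_address_book(g$bundle))
  ym <- assign_yearly_locations(book, g$bundle$moves, g$bundle$years)
  expect_equal(nrow(ym), nrow(g$bundle$years))
  expect_false(any(is.na(ym$line)))
  # role changes only at move years
  changes <- ym |>
    dplyr::arrange(duns_id, year) |>
    dplyr::group_by(duns_id) |>
    dplyr::filter(move_index != dplyr::lag(move_index) |
                    (is.na(dplyr::lag(move_index)) & !is.na(move_index))) |>
    dplyr::ungroup()
  mv_key <- paste(g$bundle$moves$duns_id, g$bundle$moves$move_year)
  expect_true(all(paste(changes$duns_id, changes$year) %in% mv_key))
})

test_that("yearly locations agree with planted truth at zero noise", {
  g <- generate_registry(synth_params(n_establishments = 600, seed = 29))
  book <- suppressMessages(build_address_book(g$bundle))
  ym <- assign_yearly_locations(book, g$bundle$moves, g$bundle$years)
  # geocode the assigned addresses exactly via the mock gold engine
  cand <- mock_provider(g$city, failure_rate = 0)(
    book |> dplyr::select(duns_id, role, move_index, line, zip5))
  best <- merge_geocodes(cand)
  placed <- ym |>
    dplyr::inner_join(best, by = c("duns_id", "role", "move_index"))
  placed <- dplyr::bind_cols(placed,
                             project_and_round(placed$lat, placed$lon))
  cmp <- placed |>
    dplyr::inner_join(g$truth$locations, by = c("duns_id", "year"),
                      suffix = c("", ".true"))
  expect_equal(nrow(cmp), nrow(g$bundle$years))
  expect_true(all(cmp$x == cmp$x.true & cmp$y == cmp$y.true))
})

test_that("mover with out-of-order move years is rejected", {
  b <- toy_bundle()
  mv <- dplyr::bind_rows(
    b$moves,
    dplyr::mutate(b$moves, move_index = 2L, move_year = 1990L))
  book <- suppressMessages(build_address_book(
    registry_bundle(b$establishments, b$years, mv, b$first_address,
                    b$recent_address)))
  expect_error(assign_yearly_locations(book, mv, b$years),
               class = "bizscape_error_moves")
})
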