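#' The synthetic city underlying generated registries
#'
#' Generated registries live on a rectangular street grid: `n_x` address
#' positions along each of `n_y` named streets, sites spaced
#' `spacing` metres apart on a planar (UTM-like) grid, partitioned into
#' rectangular zip zones. The grid makes the significant-move predicate
#' controllable on both margins (street change, zip change) and gives
#' every address an exact, recoverable ground-truth coordinate. Street
#' names carry abbreviated suffixes in their primary version and expanded
#' suffixes in the alternate version, exercising address normalisation.
#'
#' @param n_x,n_y Grid extent (address positions per street, streets).
#' @param spacing Site spacing in metres (a multiple of 10, so true
#'   locations sit exactly on the deduplication grid).
#' @param x0,y0 Planar offset of the grid origin, metres (defaults sit
#'   inside UTM zone 18N at New York latitudes).
#' @return A `bizscape_city` list.
#' @export
synthetic_city <- function(n_x = 40, n_y = 30, spacing = 200,
                           x0 = 560000, y0 = 4490000) {
  stopifnot(spacing %% 10 == 0)
  bases <- c("MAIN", "OAK", "MAPLE", "CEDAR", "ELM", "WASHINGTON",
             "LINCOLN", "PARK", "LAKE", "HILL", "RIVER", "CHURCH",
             "MARKET", "SPRING", "FRANKLIN", "HIGHLAND", "JEFFERSON",
             "MADISON", "UNION", "PROSPECT", "WALNUT", "CHESTNUT",
             "WILLOW", "SUNSET", "BROADWAY", "GRAND", "SUMMIT",
             "VALLEY", "MEADOWBROOK", "ATLANTIC")
  sfx <- tibble(abbrev = c("ST", "AVE", "BLVD", "RD", "DR",
                           "LN", "CT", "PL", "TER", "PKWY"),
                full = c("STREET", "AVENUE", "BOULEVARD", "ROAD", "DRIVE",
                         "LANE", "COURT", "PLACE", "TERRACE", "PARKWAY"))
  stopifnot(n_y <= length(bases))
  streets <- tibble(iy = seq_len(n_y),
                    base = bases[seq_len(n_y)],
                    abbrev = sfx$abbrev[(seq_len(n_y) - 1L) %% nrow(sfx) + 1L],
                    full = sfx$full[(seq_len(n_y) - 1L) %% nrow(sfx) + 1L])
  structure(list(n_x = n_x, n_y = n_y, spacing = spacing,
                 x0 = x0, y0 = y0, streets = streets,
                 zip_nx = 8L, zip_ny = 6L),
            class = "bizscape_city")
}

site_xy <- function(ix, iy, city) {
  tibble(x = city$x0 + ix * city$spacing, y = city$y0 + iy * city$spacing)
}

site_zip <- function(ix, iy, city) {
  zx <- (ix - 1L) %/% city$zip_nx
  zy <- (iy - 1L) %/% city$zip_ny
  sprintf("%05d", 10001L + zx * 10L + zy)
}

zip_centroid <- function(zip, city) {
  z <- as.integer(zip) - 10001L
  zx <- z %/% 10L
  zy <- z %% 10L
  cx <- city$x0 + (zx * city$zip_nx + (city$zip_nx + 1) / 2) * city$spacing
  cy <- city$y0 + (zy * city$zip_ny + (city$zip_ny + 1) / 2) * city$spacing
  tibble(x = round_to_grid(cx), y = round_to_grid(cy))
}

site_address <- function(ix, iy, city, version = c("primary", "alternate")) {
  version <- match.arg(version)
  st <- city$streets[iy, ]
  suffix <- if (version == "primary") st$abbrev else st$full
  paste(100L + ix, st$base, suffix)
}

# Inverse of site_address on normalised strings (normalisation expands
# street suffixes, so the suffix token is always the full form); NA where
# unparseable.
parse_site_address <- function(line, city) {
  norm <- normalize_address(line)
  parts <- stringr::str_match(norm, "^([0-9]+) ([A-Z]+) ([A-Z]+)$")
  ix <- suppressWarnings(as.integer(parts[, 2])) - 100L
  iy <- match(parts[, 3], city$streets$base)
  ok <- !is.na(ix) & !is.na(iy) & ix >= 1 & ix <= city$n_x &
    !is.na(parts[, 4]) &
    parts[, 4] == city$streets$full[ifelse(is.na(iy), 1L, iy)]
  tibble(ix = ifelse(ok, ix, NA_integer_), iy = ifelse(ok, iy, NA_integer_))
}

#' Parameters for the synthetic registry generator
#'
#' Encodes the error processes a real longitudinal establishment
#' registry exhibits: yearly SIC churn, missing SIC years, significant
#' moves, delivery geocodes whose precision improves over calendar
#' years, and co-location of same-category businesses. Defaults mirror a
#' documented large-registry profile: 21 annual snapshots 1990-2010,
#' 10 % of businesses with at least one significant move, per-year SIC
#' deviation rate such that roughly 7.7 % of businesses ever change
#' primary SIC, and zip-level-only delivery geocode shares falling from
#' 31 % (1990) through 16 % (2000) to 2 % (2010).
#'
#' @param n_establishments Number of businesses to generate.
#' @param year_range Inclusive pair of calendar years.
#' @param move_probability Probability a (multi-year) business has at
#'   least one significant move.
#' @param sic_churn_rate Per reporting-year probability that the
#'   reported SIC deviates from the true SIC.
#' @param sic_missing_rate Per active-year probability that no SIC is
#'   reported.
#' @param zip_only_fraction_by_year Named numeric map (year -> fraction
#'   of delivery geocodes at zip precision); linearly interpolated
#'   between the named years.
#' @param colocation_cluster_rate Fraction of categorized businesses
#'   placed at the site of an existing same-category business.
#' @param category_mix Named weights over category labels (must include
#'   every label used; `"uncategorized"` allowed); normalised to sum
#'   to 1.
#' @param preserve_majority Cap SIC deviations per business so the true
#'   SIC always retains an inclusive 75 % majority of reporting years
#'   (used to study recovery under majority-preserving churn).
#' @param seed Integer seed; the generator is bit-reproducible.
#' @return A validated `bizscape_synth_params` list.
#' @export
synth_params <- function(n_establishments = 2000,
                         year_range = c(1990, 2010),
                         move_probability = 0.10,
                         sic_churn_rate = 0.0129,
                         sic_missing_rate = 0.05,
                         zip_only_fraction_by_year = c("1990" = 0.31,
                                                       "2000" = 0.16,
                                                       "2010" = 0.02),
                         colocation_cluster_rate = 0.15,
                         category_mix = NULL,
                         preserve_majority = FALSE,
                         seed = 1L) {
  if (is.null(category_mix)) {
    category_mix <- c(
      "uncategorized" = 0.60,
      "Office or clinic of health practitioner" = 0.10,
      "Convenience store or small grocery store" = 0.08,
      "Other restaurant\u2014not fast food, not pizza" = 0.06,
      "Fast food restaurant" = 0.04,
      "Large supermarket" = 0.03,
      "Vigorous physical activity venue" = 0.03,
      "Light/moderate physical activity venue" = 0.03,
      "Multi-use physical activity venue" = 0.02,
      "Pizza restaurant" = 0.005,
      "Bank" = 0.005)
  }
  p <- list(n_establishments = as.integer(n_establishments),
            year_range = as.integer(year_range),
            move_probability = move_probability,
            sic_churn_rate = sic_churn_rate,
            sic_missing_rate = sic_missing_rate,
            zip_only_fraction_by_year = zip_only_fraction_by_year,
            colocation_cluster_rate = colocation_cluster_rate,
            category_mix = category_mix / sum(category_mix),
            preserve_majority = isTRUE(preserve_majority),
            seed = as.integer(seed))
  probs <- c(p$move_probability, p$sic_churn_rate, p$sic_missing_rate,
             p$colocation_cluster_rate, p$zip_only_fraction_by_year)
  if (any(probs < 0 | probs > 1)) {
    abort("All generator probabilities must lie in [0, 1]",
          class = "bizscape_error_config")
  }
  if (p$n_establishments < 1) {
    abort("n_establishments must be positive", class = "bizscape_error_config")
  }
  if (p$year_range[1] > p$year_range[2]) {
    abort("Degenerate year_range (start > end)",
          class = "bizscape_error_config")
  }
  if (any(p$category_mix < 0)) {
    abort("category_mix weights must be nonnegative",
          class = "bizscape_error_config")
  }
  structure(p, class = "bizscape_synth_params")
}

#' Category recipes used by the generator
#'
#' For every category label the generator can plant, a concrete 8-digit
#' true SIC, employee and sales ranges consistent with the shipped
#' template definitions (a planted large supermarket always clears the
#' template's size thresholds; a convenience store never does), and name
#' stems that respect the template's name rules (multi-use venues carry
#' YMCA/JCC-style tokens and are the name-rule pathway).
#'
#' @return Tibble: `category`, `sic`, `emp_lo`, `emp_hi`, `sales_lo`,
#'   `sales_hi`, `stems` (list-column).
#' @export
synth_recipes <- function() {
  tibble(
    category = c("uncategorized",
                 "Office or clinic of health practitioner",
                 "Convenience store or small grocery store",
                 "Other restaurant\u2014not fast food, not pizza",
                 "Fast food restaurant",
                 "Large supermarket",
                 "Vigorous physical activity venue",
                 "Light/moderate physical activity venue",
                 "Multi-use physical activity venue",
                 "Pizza restaurant",
                 "Bank"),
    sic = c("73890000", "80110000", "54110300", "58120000", "58120300",
            "54110000", "79910100", "79330000", "86410000", "58120500",
            "60210000"),
    emp_lo = c(1, 2, 2, 4, 5, 55, 2, 3, 5, 3, 5),
    emp_hi = c(10, 9, 6, 20, 30, 220, 15, 18, 40, 12, 25),
    sales_lo = c(5e4, 2e5, 1e5, 2e5, 3e5, 3e6, 1e5, 2e5, 3e5, 1.5e5, 1e6),
    sales_hi = c(5e5, 9e5, 9e5, 1.5e6, 2e6, 4e7, 1e6, 1.5e6, 3e6, 9e5, 2e7),
    stems = list(
      c("CONSULTING GROUP", "HOLDINGS", "TRADING CO", "MANAGEMENT SERVICES"),
      c("MEDICAL ASSOCIATES", "FAMILY PRACTICE", "HEALTH CENTER",
        "INTERNAL MEDICINE"),
      c("DELI GROCERY", "CORNER MARKET", "FOOD MART", "MINI MART"),
      c("DINER", "TRATTORIA", "GRILL", "BISTRO"),
      c("BURGER EXPRESS", "FRIED CHICKEN", "TACO HOUSE", "SANDWICH SHOP"),
      c("SUPERMARKET", "FOOD WORLD", "FRESH MARKET", "GROCERY EMPORIUM"),
      c("FITNESS CENTER", "MARTIAL ARTS ACADEMY", "BOXING GYM", "SWIM CLUB"),
      c("BOWLING LANES", "GOLF CLUB", "BILLIARDS HALL", "YOGA STUDIO"),
      c("YMCA", "YWCA", "JCC", "JEWISH COMMUNITY CENTER"),
      c("PIZZA", "PIZZERIA", "PIZZA KITCHEN", "BRICK OVEN PIZZA"),
      c("NATIONAL BANK", "SAVINGS BANK", "TRUST COMPANY", "COMMUNITY BANK")))
}

interp_fraction <- function(year, map) {
  ky <- as.integer(names(map))
  stats::approx(ky, as.numeric(map), xout = year, rule = 2)$y
}

#' Generate a synthetic registry with planted ground truth
#'
#' Produces a [registry_bundle()] plus a truth table so that every
#' downstream stage — address book, geocode merging, precision
#' filtering, categorisation, collapsing, counting — has a recoverable
#' right answer. With a fixed seed the output is bit-identical across
#' runs; realised mover and churn fractions converge to their parameters
#' as n grows.
#'
#' @param params A [synth_params()] object.
#' @param city A [synthetic_city()].
#' @return List with `bundle` (a `nets_registry`), `truth` (list of
#'   tibbles `businesses` — `duns_id`, `true_category`, `true_sic`,
#'   `is_mover`, `collapse_group` — and `locations` — `duns_id`, `year`,
#'   `x`, `y`), and `city`.
#' @export
generate_registry <- function(params = synth_params(),
                              city = synthetic_city()) {
  stopifnot(inherits(params, "bizscape_synth_params"))
  with_seed(params$seed, generate_registry_impl(params, city))
}

generate_registry_impl <- function(p, city) {
  n <- p$n_establishments
  y0 <- p$year_range[1]; y1 <- p$year_range[2]
  span_years <- y1 - y0 + 1L
  recipes <- synth_recipes()
  mix <- p$category_mix
  unknown <- setdiff(names(mix), recipes$category)
  if (length(unknown)) {
    abort(paste0("No generator recipe for categories: ",
                 paste(unknown, collapse = ", ")),
          class = "bizscape_error_config")
  }

  duns <- sprintf("%09d", sample.int(999999999L, n))
  category <- sample(names(mix), n, replace = TRUE, prob = mix)
  ri <- match(category, recipes$category)

  start <- sample(y0:y1, n, replace = TRUE)
  dur <- 1L + stats::rgeom(n, 1 / 12)
  end <- pmin(start + dur - 1L, y1)

  # home sites; a share of categorized businesses co-locate with an
  # earlier same-category business
  ix <- sample.int(city$n_x, n, replace = TRUE)
  iy <- sample.int(city$n_y, n, replace = TRUE)
  coloc <- runif(n) < p$colocation_cluster_rate & category != "uncategorized"
  for (cat in unique(category[coloc])) {
    members <- which(category == cat)
    targets <- which(coloc & category == cat)
    for (b in targets) {
      hosts <- members[members != b]
      if (length(hosts)) {
        h <- hosts[sample.int(length(hosts), 1)]
        ix[b] <- ix[h]; iy[b] <- iy[h]
      }
    }
  }

  # significant-move schedules (loop only over movers; vectors, not
  # per-business frames, to stay fast at registry scale)
  can_move <- end > start
  is_mover <- runif(n) < p$move_probability & can_move
  k_probs <- 0.55^(0:7); k_probs <- k_probs / sum(k_probs)
  mv_b <- integer(); mv_k <- integer(); mv_year <- integer()
  mv_oix <- integer(); mv_oiy <- integer()
  mv_dix <- integer(); mv_diy <- integer()
  for (b in which(is_mover)) {
    kmax <- min(8L, end[b] - start[b])
    k <- min(sample.int(8L, 1, prob = k_probs), kmax)
    yr_rng <- (start[b] + 1L):end[b]
    myrs <- sort(yr_rng[sample.int(length(yr_rng), k)])
    cur_ix <- ix[b]; cur_iy <- iy[b]
    for (m in seq_len(k)) {
      repeat {
        nix <- sample.int(city$n_x, 1); niy <- sample.int(city$n_y, 1)
        if (niy != cur_iy &&
            site_zip(nix, niy, city) != site_zip(cur_ix, cur_iy, city)) break
      }
      mv_b <- c(mv_b, b); mv_k <- c(mv_k, m); mv_year <- c(mv_year, myrs[m])
      mv_oix <- c(mv_oix, cur_ix); mv_oiy <- c(mv_oiy, cur_iy)
      mv_dix <- c(mv_dix, nix); mv_diy <- c(mv_diy, niy)
      cur_ix <- nix; cur_iy <- niy
    }
  }
  mv <- tibble(.b = mv_b, move_index = mv_k, move_year = mv_year,
               o_ix = mv_oix, o_iy = mv_oiy, d_ix = mv_dix, d_iy = mv_diy)

  # true location per active business-year: start at the home site, then
  # overwrite from each move year onward (moves applied in order)
  len <- end - start + 1L
  offset <- cumsum(len) - len
  locations <- tibble(duns_id = rep(duns, len),
                      year = sequence(len, from = start),
                      ix = rep(ix, len), iy = rep(iy, len))
  for (r in seq_len(nrow(mv))) {
    b <- mv$.b[r]
    rows <- (offset[b] + (mv$move_year[r] - start[b] + 1L)):(offset[b] + len[b])
    locations$ix[rows] <- mv$d_ix[r]
    locations$iy[rows] <- mv$d_iy[r]
  }
  locations <- bind_cols(locations,
                         site_xy(locations$ix, locations$iy, city))
  last_site <- tibble(ix = locations$ix[cumsum(len)],
                      iy = locations$iy[cumsum(len)])

  # yearly SIC reporting with churn and missingness
  years_tbl <- locations |> select("duns_id", "year")
  bi <- match(years_tbl$duns_id, duns)
  true_sic <- recipes$sic[ri]
  missing <- runif(nrow(years_tbl)) < p$sic_missing_rate
  deviate <- runif(nrow(years_tbl)) < p$sic_churn_rate & !missing
  if (p$preserve_majority) {
    dev_df <- tibble(row = seq_len(nrow(years_tbl)),
                     duns_id = years_tbl$duns_id,
                     missing = missing, deviate = deviate)
    caps <- dev_df |>
      group_by(.data$duns_id) |>
      summarise(cap = floor(0.25 * sum(!.data$missing)), .groups = "drop")
    dev_df <- dev_df |> left_join(caps, by = "duns_id")
    over <- dev_df |>
      filter(.data$deviate) |>
      group_by(.data$duns_id) |>
      mutate(ord = row_number()) |>
      ungroup() |>
      filter(.data$ord > .data$cap)
    deviate[over$row] <- FALSE
  }
  other_sic <- function(cat) {
    pool <- recipes$sic[recipes$category != cat]
    pool[sample.int(length(pool), 1)]
  }
  sic <- true_sic[bi]
  if (any(deviate)) {
    sic[deviate] <- vapply(category[bi][deviate], other_sic, character(1))
  }
  sic[missing] <- NA_character_

  # sales and employees: stable base with mild yearly jitter
  emp_base <- round(runif(n, recipes$emp_lo[ri], recipes$emp_hi[ri]))
  sales_base <- round(runif(n, recipes$sales_lo[ri], recipes$sales_hi[ri]), -3)
  employees <- pmax(1L, as.integer(round(
    emp_base[bi] * (1 + runif(nrow(years_tbl), -0.1, 0.1)))))
  employees <- pmax(employees,
                    as.integer(ceiling(recipes$emp_lo[ri][bi])))
  sales <- round(pmax(sales_base[bi] * (1 + runif(nrow(years_tbl),
                                                  -0.1, 0.1)),
                      recipes$sales_lo[ri][bi]), -2)
  estimated <- runif(nrow(years_tbl)) < 0.10

  years <- tibble(duns_id = years_tbl$duns_id, year = years_tbl$year,
                  sic = sic, sales = sales, employees = employees,
                  estimated = estimated)

  # company / trade names
  prefixes <- c("EMPIRE", "HUDSON", "LIBERTY", "METRO", "RIVERSIDE",
                "GOTHAM", "HARBOR", "PARKSIDE", "CITYWIDE", "TRISTATE",
                "BOROUGH", "GARDEN STATE")
  stem <- vapply(ri, function(i) {
    s <- recipes$stems[[i]]
    s[sample.int(length(s), 1)]
  }, character(1))
  company <- paste(sample(prefixes, n, replace = TRUE), stem)
  trade <- ifelse(runif(n) < 0.35, paste0(stem, " ", 100L + ix), NA_character_)

  # addresses: first and most recent strings, with mixed string versions
  first_site <- tibble(ix = ix, iy = iy)
  use_alt <- runif(n) < 0.3
  addr_of <- function(s, version) {
    vapply(seq_len(n), function(b) {
      site_address(s$ix[b], s$iy[b], city,
                   if (version[b]) "alternate" else "primary")
    }, character(1))
  }
  first_address <- tibble(
    duns_id = duns,
    line = addr_of(first_site, use_alt),
    alt = addr_of(first_site, !use_alt),
    zip5 = site_zip(first_site$ix, first_site$iy, city))
  recent_address <- tibble(
    duns_id = duns,
    line = addr_of(last_site, rep(FALSE, n)),
    alt = addr_of(last_site, rep(TRUE, n)),
    zip5 = site_zip(last_site$ix, last_site$iy, city))

  moves <- if (nrow(mv)) {
    tibble(duns_id = duns[mv$.b],
           move_index = mv$move_index,
           move_year = mv$move_year,
           origin_line = site_address_vec(mv$o_ix, mv$o_iy, city, "primary"),
           origin_alt = site_address_vec(mv$o_ix, mv$o_iy, city, "alternate"),
           origin_zip5 = site_zip(mv$o_ix, mv$o_iy, city),
           dest_line = site_address_vec(mv$d_ix, mv$d_iy, city, "primary"),
           dest_alt = site_address_vec(mv$d_ix, mv$d_iy, city, "alternate"),
           dest_zip5 = site_zip(mv$d_ix, mv$d_iy, city))
  } else empty_moves()

  vendor <- vendor_geocodes_for(duns, start, end, first_site, last_site,
                                mv, p, city)

  bundle <- registry_bundle(
    establishments = tibble(duns_id = duns, company_name = company,
                            trade_name = trade),
    years = years, moves = moves,
    first_address = first_address, recent_address = recent_address,
    vendor_geocodes = vendor)
  truth <- list(
    businesses = tibble(duns_id = duns, true_category = category,
                        true_sic = true_sic, is_mover = is_mover,
                        collapse_group = duns),
    locations = locations |> select("duns_id", "year", "x", "y"))
  list(bundle = bundle, truth = truth, city = city)
}

site_address_vec <- function(ix, iy, city, version) {
  vapply(seq_along(ix),
         function(i) site_address(ix[i], iy[i], city, version),
         character(1))
}

# Delivery-supplied geocodes: one per location-role, precision drawn by
# the calendar year the role enters force (zip-level share interpolated
# from the parameter map), zip-precision rows placed at the zip centroid,
# street-level rows jittered around the true site.
vendor_geocodes_for <- function(duns, start, end, first_site, last_site,
                                mv, p, city) {
  rows <- bind_rows(
    tibble(duns_id = duns, role = "first", move_index = NA_integer_,
           year = start, ix = first_site$ix, iy = first_site$iy),
    tibble(duns_id = duns, role = "most_recent", move_index = NA_integer_,
           year = end, ix = last_site$ix, iy = last_site$iy),
    if (!is.null(mv) && nrow(mv)) bind_rows(
      tibble(duns_id = duns[mv$.b], role = "origin",
             move_index = mv$move_index, year = mv$move_year,
             ix = mv$o_ix, iy = mv$o_iy),
      tibble(duns_id = duns[mv$.b], role = "destination",
             move_index = mv$move_index, year = mv$move_year,
             ix = mv$d_ix, iy = mv$d_iy)))
  zf <- interp_fraction(rows$year, p$zip_only_fraction_by_year)
  at_zip <- runif(nrow(rows)) < zf
  prec_pool <- c("block_face", "street_segment", "block_group",
                 "tract_centroid")
  prec_prob <- c(0.45, 0.35, 0.12, 0.08)
  precision <- ifelse(at_zip, "zip",
                      sample(prec_pool, nrow(rows), replace = TRUE,
                             prob = prec_prob))
  jit_sd <- c(block_face = 15, street_segment = 40, block_group = 200,
              tract_centroid = 400, zip = 0)[precision]
  xy_true <- site_xy(rows$ix, rows$iy, city)
  zc <- zip_centroid(site_zip(rows$ix, rows$iy, city), city)
  x <- ifelse(at_zip, zc$x, xy_true$x + rnorm(nrow(rows), 0, jit_sd))
  y <- ifelse(at_zip, zc$y, xy_true$y + rnorm(nrow(rows), 0, jit_sd))
  ll <- unproject_xy(x, y)
  tibble(duns_id = rows$duns_id, role = rows$role,
         move_index = rows$move_index, source = "vendor_supplied",
         lat = ll$lat, lon = ll$lon, precision = precision)
}

#' Plant exact co-located duplicates
#'
#' Adds `k_per_site - 1` duplicate records for each of a set of
#' categorized host businesses: same category, same site, same activity
#' years and SIC series, with the name perturbed by suffix/punctuation
#' edits only (category-relevant tokens preserved). The truth table
#' records the collapse group, so `raw - collapsed` counts are exactly
#' predictable.
#'
#' @param registry A list with `bundle` and `truth` (as returned by
#'   [generate_registry()]).
#' @param k_per_site Total records per duplicated site (1 = no-op).
#' @param n_sites Number of host businesses to duplicate (default: all
#'   categorized businesses).
#' @param seed Integer seed.
#' @return The registry list with augmented `bundle` and `truth`.
#' @export
plant_duplicates <- function(registry, k_per_site, n_sites = NULL,
                             seed = 1L) {
  stopifnot(k_per_site >= 1)
  if (k_per_site == 1) return(registry)
  with_seed(seed, plant_duplicates_impl(registry, k_per_site, n_sites))
}

plant_duplicates_impl <- function(registry, k_per_site, n_sites) {
  bundle <- registry$bundle
  truth <- registry$truth
  eligible <- truth$businesses |>
    filter(.data$true_category != "uncategorized") |>
    pull("duns_id")
  if (!is.null(n_sites)) {
    if (n_sites > length(eligible)) {
      abort("n_sites exceeds the number of categorized businesses",
            class = "bizscape_error_config")
    }
    eligible <- sample(eligible, n_sites)
  }
  n_new <- length(eligible) * (k_per_site - 1L)
  if (n_new == 0L) return(registry)
  taken <- as.integer(bundle$establishments$duns_id)
  pool <- setdiff(sample.int(999999999L, n_new + length(taken)), taken)
  new_ids <- sprintf("%09d", pool[seq_len(n_new)])
  host <- rep(eligible, each = k_per_site - 1L)

  perturb <- function(name, i) {
    switch((i %% 4L) + 1L,
           paste0(name, " LLC"),
           paste0(name, " INC"),
           gsub(" ", " - ", name, fixed = TRUE),
           paste0(name, " #", i))
  }
  est <- bundle$establishments
  hrow <- est[match(host, est$duns_id), ]
  new_est <- tibble(duns_id = new_ids,
                    company_name = vapply(seq_len(n_new), function(i) {
                      perturb(hrow$company_name[i], i)
                    }, character(1)),
                    trade_name = hrow$trade_name)
  dup_join <- tibble(duns_id = host, new_id = new_ids)
  copy <- function(tab) {
    tab |>
      inner_join(dup_join, by = "duns_id",
                 relationship = "many-to-many") |>
      mutate(duns_id = .data$new_id) |>
      select(-"new_id")
  }
  bundle2 <- registry_bundle(
    establishments = bind_rows(est, new_est),
    years = bind_rows(bundle$years, copy(bundle$years)),
    moves = bind_rows(bundle$moves, copy(bundle$moves)),
    first_address = bind_rows(bundle$first_address,
                              copy(bundle$first_address)),
    recent_address = bind_rows(bundle$recent_address,
                               copy(bundle$recent_address)),
    vendor_geocodes = bind_rows(bundle$vendor_geocodes,
                                copy(bundle$vendor_geocodes)),
    issues = bundle$issues)
  tb <- truth$businesses
  new_tb <- tb[match(host, tb$duns_id), ] |>
    mutate(duns_id = new_ids, collapse_group = host)
  truth2 <- list(
    businesses = bind_rows(tb, new_tb),
    locations = bind_rows(truth$locations, copy(truth$locations)))
  out <- registry
  out$bundle <- bundle2
  out$truth <- truth2
  out
}

#' Deterministic mock geocoding provider for the synthetic city
#'
#' Real geocoding engines are pluggable providers returning candidate
#' lists; this one understands the synthetic city's address grammar and
#' returns exact point-level coordinates for any parseable address (an
#' optional failure rate knocks out a random subset, as real engines
#' fail to match some addresses). Use it to exercise the merge /
#' precision / re-geocoding machinery with a known right answer.
#'
#' @param city A [synthetic_city()].
#' @param source Source tier label (see [source_priority()]).
#' @param failure_rate Probability an address fails to geocode.
#' @param seed Seed for the failure draw.
#' @return A provider: `function(addresses)` taking a tibble with
#'   `duns_id`, `role`, `move_index`, `line`, `zip5` and returning a
#'   geocode-candidate tibble.
#' @export
mock_provider <- function(city = synthetic_city(), source = "gold_local",
                          failure_rate = 0, seed = 1L) {
  force(city); force(source); force(failure_rate); force(seed)
  function(addresses) {
    parsed <- parse_site_address(addresses$line, city)
    ok <- !is.na(parsed$ix)
    if (failure_rate > 0) {
      fail <- with_seed(seed, runif(nrow(addresses)) < failure_rate)
      ok <- ok & !fail
    }
    xy <- site_xy(parsed$ix[ok], parsed$iy[ok], city)
    ll <- unproject_xy(xy$x, xy$y)
    tibble(duns_id = addresses$duns_id[ok],
           role = addresses$role[ok],
           move_index = addresses$move_index[ok],
           source = source,
           lat = ll$lat, lon = ll$lon,
           precision = "point")
  }
}

#' Rectangular county partition of the synthetic city
#'
#' Splits the city's bounding box into an `nx` by `ny` grid of
#' rectangular "county" polygons (planar coordinates), for use as the
#' study region of a synthetic run.
#'
#' @param city A [synthetic_city()].
#' @param nx,ny Number of counties along each axis.
#' @param margin Extra margin around the grid, metres.
#' @return A `bizscape_region` with features `county_1`, `county_2`, ...
#' @export
synthetic_region <- function(city = synthetic_city(), nx = 2, ny = 2,
                             margin = 400) {
  x_lo <- city$x0 + city$spacing - margin
  x_hi <- city$x0 + city$n_x * city$spacing + margin
  y_lo <- city$y0 + city$spacing - margin
  y_hi <- city$y0 + city$n_y * city$spacing + margin
  xs <- seq(x_lo, x_hi, length.out = nx + 1)
  ys <- seq(y_lo, y_hi, length.out = ny + 1)
  feats <- list()
  k <- 0
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1
      ring <- rbind(c(xs[i], ys[j]), c(xs[i + 1], ys[j]),
                    c(xs[i + 1], ys[j + 1]), c(xs[i], ys[j + 1]),
                    c(xs[i], ys[j]))
      feats[[paste0("county_", k)]] <- list(ring)
    }
  }
  region_from_rings(feats)
}
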