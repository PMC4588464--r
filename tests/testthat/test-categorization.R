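defs <- load_category_definitions()

attrs1 <- function(sic, company = "SOME NAME", trade = NA_character_,
                   sales = NA_real_, employees = NA_integer_) {
  tibble::tibble(sic = sic, company_name = company, trade_name = trade,
                 sales = sales, employees = employees)
}

test_that("the majority rule threshold is inclusive at exactly 75 %", {
  m <- majority_sic(rep(c("A", "B"), c(8, 2)), 1991:2000)
  expect_equal(m$sic, "A")
  expect_equal(m$fraction, 0.80)
  # 3 of 4 years: exactly 75 %, qualifies
  m2 <- majority_sic(c("A", "A", "A", "B"), 1991:1994)
  expect_equal(m2$sic, "A")
  expect_equal(m2$fraction, 0.75)
  # 6 of 10: no majority
  m3 <- majority_sic(rep(c("A", "B"), c(6, 4)), 1991:2000)
  expect_true(is.na(m3$sic))
  expect_equal(m3$fraction, 0.60)
  # modal ties resolve toward the most recently reported code
  m4 <- majority_sic(c("A", "A", "B", "B"), c(1991, 1992, 1993, 1994),
                     threshold = 0.5)
  expect_equal(m4$sic, "B")
  expect_error(majority_sic(c(NA, NA), 1:2),
               class = "bizscape_error_input")
})

test_that("overall SIC falls back to the most recent code", {
  expect_equal(resolve_overall_sic(rep("A", 5), 1990:1994)$sic, "A")
  r <- resolve_overall_sic(c("A", "A", "A", "B", "B"), 1990:1994)
  expect_equal(r$sic, "B")          # 60 % early majority loses to recency
  expect_equal(r$basis, "most_recent")
  one <- resolve_overall_sic("C", 2005)
  expect_equal(one$sic, "C")
  expect_equal(one$basis, "majority")
  none <- resolve_overall_sic(NA_character_, 2005)
  expect_equal(none$basis, "no_sic")
})

test_that("definitions match on SIC, name rules and size thresholds", {
  multiuse <- defs[defs$name == "Multi-use physical activity venue", ]
  # generic SIC, but the name carries YMCA: name rule fires
  expect_true(match_definition(attrs1("86410000", "EMPIRE YMCA"), multiuse))
  expect_false(match_definition(attrs1("86410000", "EMPIRE CLUB"), multiuse))

  super <- defs[defs$name == "Large supermarket", ]
  # grocery SIC below the supermarket size floor fails
  expect_false(match_definition(
    attrs1("54110000", sales = 3e6, employees = 10), super))
  expect_true(match_definition(
    attrs1("54110000", sales = 3e6, employees = 80), super))
  # missing size fields fail a threshold-bearing definition
  expect_false(match_definition(attrs1("54110000"), super))

  # SIC in no definition, no name match
  expect_false(any(vapply(seq_len(nrow(defs)), function(i) {
    match_definition(attrs1("73890000", "EMPIRE HOLDINGS"), defs[i, ])
  }, logical(1))))

  # name excludes beat SIC matches
  ff <- defs[defs$name == "Fast food restaurant", ]
  expect_true(match_definition(attrs1("58120300", "BURGER EXPRESS"), ff))
  expect_false(match_definition(attrs1("58120300", "EMPIRE PIZZA"), ff))
})

test_that("the lowest priority rank wins a multi-category match", {
  out <- assign_category(
    attrs1("54110000", sales = 5e6, employees = 100), defs)
  expect_equal(out$category, "Large supermarket")
  small <- assign_category(
    attrs1("54110000", sales = 2e5, employees = 4), defs)
  expect_equal(small$category, "Convenience store or small grocery store")
  none <- assign_category(attrs1("73890000"), defs)
  expect_equal(none$category, "uncategorized")
  expect_equal(none$basis, "none")
  # duplicated ranks are a config error
  dup <- defs
  dup$priority[2] <- dup$priority[1]
  expect_error(assign_category(attrs1("5812*"), dup),
               class = "bizscape_error_config")
  expect_error(load_category_definitions(
    list(categories = list(list(name = "a", priority = 1, sic = "1*"),
                           list(name = "b", priority = 1, sic = "2*")))),
    class = "bizscape_error_config")
})

test_that("every business gets exactly one category (accounting identity)", {
  g <- generate_registry(synth_params(n_establishments = 800, seed = 41))
  out <- categorize_overall(g$bundle, defs)
  expect_equal(nrow(out), 800)
  expect_equal(dplyr::n_distinct(out$duns_id), 800)
  tab <- dplyr::count(out, category)
  expect_equal(sum(tab$n), 800)
  expect_equal(sum(tab$n[tab$category != "uncategorized"]) +
                 sum(tab$n[tab$category == "uncategorized"]), 800)
})

test_that("zero-churn synthetic registries are categorized perfectly", {
  g <- generate_registry(synth_params(n_establishments = 1000,
                                      sic_churn_rate = 0,
                                      sic_missing_rate = 0, seed = 43))
  out <- categorize_overall(g$bundle, defs) |>
    dplyr::inner_join(g$truth$businesses, by = "duns_id")
  expect_equal(mean(out$category == out$true_category), 1)
})

test_that("yearly mode equals overall mode for constant businesses", {
  g <- generate_registry(synth_params(n_establishments = 400,
                                      sic_churn_rate = 0,
                                      sic_missing_rate = 0, seed = 47))
  overall <- categorize_overall(g$bundle, defs)
  yearly <- categorize_yearly(g$bundle, defs)
  cmp <- yearly |>
    dplyr::inner_join(overall, by = "duns_id",
                      suffix = c("_y", "_o"))
  expect_equal(cmp$category_y, cmp$category_o)
})

test_that("yearly mode matches a brute-force reimplementation", {
  g <- generate_registry(synth_params(n_establishments = 250,
                                      sic_churn_rate = 0.3, seed = 53))
  got <- categorize_yearly(g$bundle, defs)
  est <- g$bundle$establishments
  # independent per-row loop over definitions in priority order
  slow_one <- function(sic, name, sales, employees) {
    for (i in order(defs$priority)) {
      d <- defs[i, ]
      sic_hit <- !is.na(sic) && any(vapply(d$sic[[1]], function(p) {
        if (grepl("\\*$", p)) startsWith(sic, sub("\\*$", "", p))
        else sic == p
      }, logical(1)))
      nm <- toupper(name)
      name_hit <- length(d$name_include[[1]]) > 0 &&
        any(vapply(d$name_include[[1]], function(p) {
          grepl(p, nm, ignore.case = TRUE)
        }, logical(1)))
      excl <- length(d$name_exclude[[1]]) > 0 &&
        any(vapply(d$name_exclude[[1]], function(p) {
          grepl(p, nm, ignore.case = TRUE)
        }, logical(1)))
      size_ok <- TRUE
      if (!is.na(d$min_employees)) {
        size_ok <- size_ok && !is.na(employees) &&
          employees >= d$min_employees
      }
      if (!is.na(d$min_sales)) {
        size_ok <- size_ok && !is.na(sales) && sales >= d$min_sales
      }
      if ((sic_hit || name_hit) && !excl && size_ok) return(d$name)
    }
    "uncategorized"
  }
  want <- g$bundle$years |>
    dplyr::left_join(est, by = "duns_id") |>
    dplyr::rowwise() |>
    dplyr::mutate(expected = slow_one(
      sic, paste(company_name,
                 ifelse(is.na(trade_name), "", trade_name)),
      sales, employees)) |>
    dplyr::ungroup()
  cmp <- got |>
    dplyr::inner_join(want |> dplyr::select(duns_id, year, expected),
                      by = c("duns_id", "year"))
  expect_equal(cmp$category, cmp$expected)
  # per-year totals line up too
  expect_equal(dplyr::count(cmp, year, category),
               dplyr::count(cmp, year, expected) |>
                 dplyr::rename(category = expected))
})

test_that("requesting a year outside all activity errors", {
  b <- toy_bundle()
  expect_error(categorize_yearly(b, defs, years = 2050),
               class = "bizscape_error_input")
  y91 <- categorize_yearly(b, defs, years = 1991)
  expect_equal(sort(unique(y91$year)), 1991L)
})

test_that("MET banding honours the printed boundaries", {
  expect_equal(met_band(5.9), "light_moderate")
  expect_equal(met_band(6.0), "vigorous")
  expect_equal(met_band(1.6), "light_moderate")
  expect_equal(met_band(c(3.5, 8)), c("light_moderate", "vigorous"))
  expect_error(met_band(1.0), class = "bizscape_error_input")
})

test_that("review sample sizes follow the three frequency strata", {
  expect_equal(review_sample_size(40), 40L)     # under 50: review all
  expect_equal(review_sample_size(100), 20L)    # 50-250: 20 %
  expect_equal(review_sample_size(300), 50L)    # over 250: flat 50
  expect_equal(review_sample_size(c(0, 49, 50, 250, 251)),
               c(0L, 49L, 10L, 50L, 50L))
  expect_equal(review_sample_size(55), 11L)     # ceiling of 20 %
  expect_error(review_sample_size(-1), class = "bizscape_error_input")
  # piecewise monotone nondecreasing within each stratum, constant
  # above 250 (the rule drops at the 50-frequency boundary by design:
  # 49 establishments are all reviewed, 50 yield a sample of 10)
  f <- review_sample_size(0:400)
  expect_true(all(diff(f[1:50]) >= 0))      # frequencies 0-49
  expect_true(all(diff(f[51:251]) >= 0))    # frequencies 50-250
  expect_true(all(f[252:401] == 50L))
})

test_that("review sampling is seeded and the 50 % rule is inclusive", {
  pool <- tibble::tibble(duns_id = sprintf("%09d", 1:120),
                         company_name = paste("BIZ", 1:120),
                         trade_name = NA_character_)
  w1 <- draw_review_sample(pool, seed = 5)
  w2 <- draw_review_sample(pool, seed = 5)
  expect_identical(w1$duns_id, w2$duns_id)
  expect_equal(nrow(w1), review_sample_size(120))
  expect_true(all(is.na(w1$relevant)))

  mark <- function(w, k) { w$relevant <- seq_len(nrow(w)) <= k; w }
  ten <- utils::head(w1, 10)
  expect_equal(evaluate_review(mark(ten, 5)), "include")  # exactly 50 %
  expect_equal(evaluate_review(mark(ten, 4)), "exclude")
  expect_error(evaluate_review(ten), class = "bizscape_error_input")
})
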