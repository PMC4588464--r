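Package: bizscape
Title: Longitudinal Business Establishment Registry Processing and
    Built-Environment Density Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning longitudinal business-establishment
    registries (NETS-style annual snapshots keyed by DUNS number) into
    analysis-ready measures of the local business environment. Builds a
    comprehensive address file with dual address-string versions and a
    significant-move timeline, merges geocode candidates from multiple
    providers by a fixed priority scheme, filters by geocoding precision
    and study region, projects coordinates to a local UTM system rounded
    to a 10 m grid, assigns establishments to mutually exclusive
    researcher-defined categories from SIC codes, names and size fields
    (with a 75 percent majority rule across years and a most-recent
    fallback), collapses co-located same-category records, and produces
    per-geography count tables with linear time trends. A synthetic
    registry generator with planted ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
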