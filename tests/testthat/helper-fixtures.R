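# Hand-constructed toy registry: 3 businesses, 1 mover (one significant
# move in 1991). Written as literal NETS-dialect TSV text so read tests
# are independent of the package's writer.

toy_tsv_lines <- function() {
  tsv <- function(...) paste(..., sep = "\t")
  list(
    establishments = c(
      tsv("dunsnumber", "company", "tradename", "address", "altaddress",
          "zipcode", "sic_1990", "sic_1991", "sic_1992",
          "sales_1990", "sales_1991", "sales_1992",
          "emp_1990", "emp_1991", "emp_1992"),
      tsv("111111111", "ACME DINER", "", "10 MAIN ST", "10 MAIN STREET",
          "10001", "58120000", "58120000", "58120000",
          "250000", "260000", "270000", "5", "5", "6"),
      tsv("222222222", "GOTHAM YMCA", "YMCA", "105 OAK AVE",
          "105 OAK AVENUE", "10002", "86410000", "86410000", "",
          "500000", "510000", "520000", "12", "12", "12"),
      tsv("333333333", "CITY BANK", "", "200 ELM ST", "200 ELM STREET",
          "10011", "60210000", "60210000", "60210000",
          "4000000", "4100000", "4200000", "9", "9", "10")),
    moves = c(
      tsv("dunsnumber", "moveindex", "moveyear", "originaddress",
          "originaltaddress", "originzip", "destaddress",
          "destaltaddress", "destzip"),
      tsv("333333333", "1", "1991", "12 MAPLE ST", "12 MAPLE STREET",
          "10001", "200 ELM ST", "200 ELM STREET", "10011")),
    first_address = c(
      tsv("dunsnumber", "address", "altaddress", "zipcode"),
      tsv("111111111", "10 Main St.", "10 MAIN STREET", "10001"),
      tsv("222222222", "105 OAK AVE", "105 OAK AVENUE", "10002"),
      tsv("333333333", "12 MAPLE ST", "12 MAPLE STREET", "10001")),
    geocodes = c(
      tsv("dunsnumber", "role", "moveindex", "source", "latitude",
          "longitude", "precision"),
      tsv("111111111", "most_recent", "", "vendor_supplied", "40.71",
          "-74.00", "block_face"),
      tsv("333333333", "destination", "1", "vendor_supplied", "40.75",
          "-73.98", "zip")))
}

write_toy_files <- function(dir, names = NULL) {
  lines <- toy_tsv_lines()
  if (is.null(names)) {
    names <- setNames(paste0(names(lines), ".tsv"), names(lines))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (k in names(lines)) {
    p <- file.path(dir, names[[k]])
    writeLines(lines[[k]], p)
    paths <- c(paths, p)
  }
  paths
}

# Small in-memory bundle built through the public constructor.
toy_bundle <- function() {
  files <- write_toy_files(withr::local_tempdir(.local_envir = parent.frame()))
  suppressMessages(read_registry(files))
}

# Sort every table so bundles can be compared independent of row order.
normalize_bundle <- function(b) {
  ord <- function(df) df[do.call(order, as.list(df)), , drop = FALSE]
  out <- lapply(b[c("establishments", "years", "moves", "first_address",
                    "recent_address", "vendor_geocodes")], function(df) {
    df <- as.data.frame(df)
    rownames(df) <- NULL
    ord(df)
  })
  out
}
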