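test_that("a well-formed DEMO row parses into typed fields", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("primaryid$caseid$fda_dt$age$age_cod$sex\n1001$100$20200101$6$YR$M",
             f, sep = "\n")
  d <- parse_quarter_table(f, "DEMO")
  expect_equal(nrow(d), 1)
  expect_equal(d$primaryid, "1001")
  expect_equal(d$age_value, 6)
  expect_equal(d$age_unit, "YR")
  expect_equal(d$sex, "M")
  expect_true(is.na(d$reporter_type)) # column absent in file
  rep <- parse_report(d)
  expect_equal(rep$rows_read, 1)
  expect_equal(rep$rows_skipped, 0)
})

test_that("schema drift: a missing column yields missing values, not errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$fda_dt$age$age_cod",
               "1001$100$20200101$6$YR"), f)
  d <- parse_quarter_table(f, "DEMO")
  expect_equal(nrow(d), 1)
  expect_true(is.na(d$sex))
  rep <- parse_report(d)
  expect_equal(rep$unknown_columns, 0)
  expect_true("sex" %in% rep$missing_columns)
})

test_that("legacy GNDR_COD header is accepted as the sex column", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$fda_dt$gndr_cod", "1$1$20100101$f"), f)
  expect_equal(parse_quarter_table(f, "DEMO")$sex, "F")
})

test_that("lenient mode skips and counts malformed rows; strict mode errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$drug_seq$role_cod$drugname$prod_ai",
               "1$1$PS$DRUG A$",
               "2$1$PS$DRUG B$AI$EXTRA$EXTRA2", # two extra fields
               "3$1$C$DRUG C$"), f)
  d <- parse_quarter_table(f, "DRUG")
  expect_equal(nrow(d), 2)
  expect_equal(parse_report(d)$rows_skipped, 1)
  expect_equal(parse_report(d)$rows_read, 3)
  expect_error(parse_quarter_table(f, "DRUG", strict = TRUE),
               "wrong field count")
})

test_that("missing-value convention: empty field round-trips to NA", {
  f <- withr::local_tempfile(fileext = ".txt")
  rec <- make_demo("1001", "100", age_value = 6, age_unit = "YR")
  write_quarter_table(rec, "DEMO", f)
  again <- parse_quarter_table(f, "DEMO", strict = TRUE)
  expect_true(is.na(again$sex))
  expect_equal(again$age_value, 6)
})

test_that("write-then-parse is the identity on every field of a bundle", {
  cfg <- synthetic_config(n_reports = 60, seed = 3, years = 2021)
  g <- generate_bundle(cfg)
  dir <- withr::local_tempdir()
  for (kind in c("DEMO", "DRUG", "REAC", "OUTC", "INDI")) {
    tab <- g$bundle[[tolower(kind)]]
    f <- file.path(dir, paste0(tolower(kind), ".txt"))
    write_quarter_table(tab, kind, f)
    back <- parse_quarter_table(f, kind, strict = TRUE)
    orig <- data.table::as.data.table(tab)[, names(back), with = FALSE]
    # numeric columns written as text: compare on parsed representation
    expect_equal(as.data.frame(back), as.data.frame(orig),
                 ignore_attr = TRUE, label = kind)
  }
})

test_that("a field containing the delimiter is rejected with the record named", {
  bad <- make_drug("77", "BAD$NAME")
  f <- withr::local_tempfile(fileext = ".txt")
  expect_error(write_quarter_table(bad, "DRUG", f), "77")
})

test_that("load_quarters concatenates quarters and tracks provenance", {
  dir <- withr::local_tempdir()
  for (q in c("2020q1", "2020q2")) {
    write_quarter_table(make_demo(paste0(q, 1:10), fda_dt = "20200205"),
                        "DEMO", file.path(dir, paste0("demo", q, ".txt")))
    write_quarter_table(make_drug(paste0(q, 1:10), "DRUG A"),
                        "DRUG", file.path(dir, paste0("drug", q, ".txt")))
    write_quarter_table(make_reac(paste0(q, 1:10), "Cough"),
                        "REAC", file.path(dir, paste0("reac", q, ".txt")))
  }
  b <- load_quarters(dir, c("2020q1", "2020q2"))
  expect_equal(nrow(b$demo), 20)
  expect_gte(length(b$provenance), 6)
})

test_that("load_quarters degenerate inputs: empty list warns, missing table errors", {
  dir <- withr::local_tempdir()
  expect_warning(b <- load_quarters(dir, character(0)), "empty quarter list")
  expect_equal(nrow(b$demo), 0)
  write_quarter_table(make_demo("1"), "DEMO",
                      file.path(dir, "demo2020q1.txt"))
  expect_error(load_quarters(dir, "2020q1"), "DRUG")
})

test_that("era tolerance: dropping a non-key column changes only missingness", {
  cfg <- synthetic_config(n_reports = 40, seed = 5, years = 2021)
  g <- generate_bundle(cfg)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "demo.txt")
  write_quarter_table(g$bundle$demo, "DEMO", f)
  full <- parse_quarter_table(f, "DEMO")
  # rewrite without the sex column
  lines <- readLines(f)
  drop_col <- which(strsplit(lines[1], "$", fixed = TRUE)[[1]] == "sex")
  pruned <- vapply(strsplit(lines, "$", fixed = TRUE), function(x)
    paste(x[-drop_col], collapse = "$"), character(1))
  writeLines(pruned, f)
  part <- parse_quarter_table(f, "DEMO")
  expect_equal(nrow(part), nrow(full))
  expect_true(all(is.na(part$sex)))
  expect_equal(part$age_value, full$age_value)
})
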