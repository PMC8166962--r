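test_that("partial dates parse at the three precisions and format back", {
  cases <- list(
    list(text = "20200115", year = 2020L, month = 1L, day = 15L,
         completeness = "full"),
    list(text = "202001", year = 2020L, month = 1L, day = NA_integer_,
         completeness = "year_month"),
    list(text = "2020", year = 2020L, month = NA_integer_,
         day = NA_integer_, completeness = "year_only"))
  for (cs in cases) {
    d <- parse_partial_date(cs$text)
    expect_equal(d$year, cs$year)
    expect_equal(d$month, cs$month)
    expect_equal(d$day, cs$day)
    expect_equal(d$completeness, cs$completeness)
    expect_equal(format(d), cs$text)
  }
})

test_that("invalid calendar dates and malformed text are rejected", {
  expect_error(parse_partial_date("20200230"), "calendar")
  expect_error(parse_partial_date("20201315"), "month")
  expect_error(parse_partial_date("2020-01-15"), "layout")
  expect_error(parse_partial_date("202"), "layout")
})

test_that("vectorised completeness and ordinal never promote partial dates", {
  x <- c("20200115", "202001", "2020", "", NA)
  expect_equal(date_completeness(x),
               c("full", "year_month", "year_only", NA, NA))
  ord <- date_ordinal(x)
  expect_equal(ord[1], as.integer(as.Date("2020-01-15")))
  expect_true(all(is.na(ord[-1])))
  # one day apart at a month boundary
  expect_equal(date_ordinal("20200301") - date_ordinal("20200229"), 1L)
})

test_that("empty files read to an empty dataset with zero totals", {
  dir <- withr::local_tempdir()
  paths <- list(demo = file.path(dir, "demo.csv"),
                drug = file.path(dir, "drug.csv"),
                reac = file.path(dir, "reac.csv"),
                hist = file.path(dir, "hist.csv"))
  write_srs_dataset(new_srs_dataset(), paths)
  ds <- read_srs_dataset(paths)
  expect_s3_class(ds, "srs_dataset")
  expect_equal(n_reports(ds), 0L)
  expect_equal(nrow(ds$drug), 0L)
  expect_equal(nrow(ds$reac), 0L)
})

test_that("validation names a duplicated demo case_id", {
  demo <- data.frame(case_id = c("A", "B", "C", "B", "D"),
                     sex = "male", age_band = "60s",
                     report_period = "2019")
  expect_error(new_srs_dataset(demo = demo), "B")
})

test_that("referential integrity and code vocabularies are enforced", {
  ds <- tiny_dataset()
  bad <- ds
  bad$reac <- rbind(bad$reac,
                    data.frame(case_id = "ZZ", pt_code = 1L, pt_name = "x",
                               onset_date = "", outcome = "recovered"))
  expect_error(validate_srs_dataset(bad), "absent from demo")
  bad2 <- ds
  bad2$drug$role_code[1] <- "main"
  expect_error(validate_srs_dataset(bad2), "role_code")
  bad3 <- ds
  bad3$reac$outcome[1] <- "cured"
  expect_error(validate_srs_dataset(bad3), "outcome")
})

test_that("a 100-report synthetic dataset round-trips through disk", {
  cfg <- one_drug_config(n = 100L, multiplier = 5, seed = 11L,
                         exposure = 0.2, background = 0.05,
                         missing_date_prob = 0.2,
                         duplicate_prescription_prob = 0.1)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- as.list(file.path(dir, c("demo.csv", "drug.csv", "reac.csv",
                                    "hist.csv")))
  names(paths) <- c("demo", "drug", "reac", "hist")
  write_srs_dataset(ds, paths)
  back <- read_srs_dataset(paths)
  for (tab in c("demo", "drug", "reac", "hist"))
    expect_equal(back[[tab]], ds[[tab]], ignore_attr = TRUE)
  # year-month dates survive at their stored precision
  ym <- grepl("^[0-9]{6}$", ds$drug$start_date)
  expect_true(any(ym))
  expect_identical(back$drug$start_date[ym], ds$drug$start_date[ym])
})

test_that("unparseable records are rejected with a count, not silently", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  paths <- as.list(file.path(dir, c("demo.csv", "drug.csv", "reac.csv",
                                    "hist.csv")))
  names(paths) <- c("demo", "drug", "reac", "hist")
  write_srs_dataset(ds, paths)
  # corrupt one drug row (unknown role) and one reac row (bad PT)
  drug <- read.csv(paths$drug, colClasses = "character")
  drug$role_code[2] <- "mystery"
  write.csv(drug, paths$drug, row.names = FALSE)
  reac <- read.csv(paths$reac, colClasses = "character")
  reac$pt_code[1] <- "not-a-code"
  write.csv(reac, paths$reac, row.names = FALSE)
  expect_warning(back <- read_srs_dataset(paths), "rejected")
  rej <- attr(back, "n_rejected")
  expect_equal(unname(rej["drug"]), 1L)
  expect_equal(unname(rej["reac"]), 1L)
  expect_equal(nrow(back$drug), nrow(ds$drug) - 1L)
})

test_that("a code-mapping file translates source labels to canonical tokens", {
  dir <- withr::local_tempdir()
  map_path <- file.path(dir, "codes.yaml")
  yaml::write_yaml(list(role_codes = list("被疑薬" = "suspected"),
                        outcome_codes = list("回復" = "recovered")),
                   map_path)
  map <- read_code_map(map_path)
  expect_equal(unname(map$role_codes[["被疑薬"]]), "suspected")
  ds <- tiny_dataset()
  paths <- as.list(file.path(dir, c("demo.csv", "drug.csv", "reac.csv",
                                    "hist.csv")))
  names(paths) <- c("demo", "drug", "reac", "hist")
  write_srs_dataset(ds, paths)
  drug <- read.csv(paths$drug, colClasses = "character")
  drug$role_code[drug$role_code == "suspected"] <- "被疑薬"
  write.csv(drug, paths$drug, row.names = FALSE, fileEncoding = "UTF-8")
  back <- read_srs_dataset(paths, code_map = map)
  expect_equal(sum(back$drug$role_code == "suspected"),
               sum(ds$drug$role_code == "suspected"))
  # mapping to an unknown canonical token is refused
  yaml::write_yaml(list(role_codes = list(x = "primary")), map_path)
  expect_error(read_code_map(map_path), "unknown canonical")
})

test_that("missing input files are fatal", {
  expect_error(read_srs_dataset(list(demo = "/nonexistent/demo.csv",
                                     drug = "x", reac = "y", hist = "z")),
               "missing input file")
})
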