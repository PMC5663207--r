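# Stats tables small enough to write by hand.
mk_stats <- function(keys, atleast, exact, n, cost = NA_real_) {
  W <- 1000
  tab <- data.table::as.data.table(list(
    key = keys, size = n,
    atleast_exposure_count = as.integer(atleast),
    exact_exposure_count = as.integer(exact)))
  tab[, fraction_exact := exact_exposure_count / atleast_exposure_count]
  tab[, fraction_all_windows := atleast_exposure_count / W]
  if (n > 1L) tab[, observe_per_expect_1s := 1.25]
  if (n > 2L) tab[, observe_per_expect_N1 := 1.1]
  tab[, estimate_drug_combo_cost_per_day := cost]
  tab
}

test_that("emitted headers match the publication layout exactly", {
  dir <- withr::local_tempdir()
  stats <- list("1" = mk_stats("alpha", 500, 400, 1L, 1.0),
                "2" = mk_stats("alpha|beta", 300, 200, 2L, 2.0),
                "3" = mk_stats("alpha|beta|gamma", 20000, 15000, 3L, 3.0))
  write_drug_records(stats, emission_policy(), dir)
  expect_identical(
    readLines(file.path(dir, "db_drugs_1s.tsv"), n = 1L),
    paste("drug_name_A", "atleast_exposure_count", "exact_exposure_count",
          "estimate_drug_cost_per_day", "fraction_exact",
          "fraction_all_windows", sep = "\t"))
  expect_identical(
    readLines(file.path(dir, "db_drugs_2s.tsv"), n = 1L),
    paste("drug_name_A", "drug_name_B", "atleast_exposure_count",
          "exact_exposure_count", "estimate_drug_cost_per_day",
          "fraction_exact", "fraction_all_windows",
          "observe_per_expect_1s", sep = "\t"))
  expect_identical(
    readLines(file.path(dir, "db_drugs_3s.tsv"), n = 1L),
    paste("drug_name_A", "drug_name_B", "drug_name_C",
          "atleast_exposure_count", "exact_exposure_count",
          "estimate_drug_cost_per_day", "fraction_exact",
          "fraction_all_windows", "observe_per_expect_1s",
          "observe_per_expect_N1", sep = "\t"))

  cls <- list("2" = mk_stats("Q01|R01", 300, 200, 2L))
  write_class_records(cls, emission_policy(), dir,
                      class_names = data.table::data.table(
                        atc_class = c("Q01", "R01"),
                        atc_class_name = c("CLASS Q", "CLASS R")))
  expect_identical(
    readLines(file.path(dir, "db_atc_classes_2s.tsv"), n = 1L),
    paste("atc_code_A", "atc_name_A", "atc_code_B", "atc_name_B",
          "atleast_exposure_count", "exact_exposure_count",
          "fraction_exact", "fraction_all_windows",
          "observe_per_expect_1s", sep = "\t"))
})

test_that("counts below the privacy threshold are masked, not printed", {
  dir <- withr::local_tempdir()
  stats <- list("2" = mk_stats("a|b", 150, 99, 2L))
  write_drug_records(stats, emission_policy(), dir)
  row <- strsplit(readLines(file.path(dir, "db_drugs_2s.tsv"))[2L], "\t")[[1L]]
  expect_identical(row[3L], "150")
  expect_identical(row[4L], "<100")
})

test_that("inclusion thresholds drop sparse large combinations", {
  dir <- withr::local_tempdir()
  stats <- list("3" = mk_stats(c("a|b|c", "a|b|d"), c(9999, 10000),
                               c(5000, 6000), 3L))
  write_drug_records(stats, emission_policy(), dir)
  lines <- readLines(file.path(dir, "db_drugs_3s.tsv"))
  expect_identical(length(lines), 2L)  # header + the qualifying row only
  expect_match(lines[2L], "^a\tb\td\t")
  # pairs are always included regardless of count
  stats2 <- list("2" = mk_stats("a|b", 5, 5, 2L))
  write_drug_records(stats2, emission_policy(), dir)
  expect_identical(length(readLines(file.path(dir, "db_drugs_2s.tsv"))), 2L)
})

test_that("rows are ordered by descending at-least count then key", {
  dir <- withr::local_tempdir()
  stats <- list("1" = mk_stats(c("b", "a", "c"), c(100, 300, 300),
                               c(100, 300, 300), 1L))
  write_drug_records(stats, emission_policy(), dir)
  lines <- readLines(file.path(dir, "db_drugs_1s.tsv"))[-1L]
  expect_identical(sub("\t.*", "", lines), c("a", "c", "b"))
})

test_that("records round-trip losslessly, including censoring", {
  dir <- withr::local_tempdir()
  stats <- list("2" = mk_stats(c("a|b", "a|c", "b|c"),
                               c(25000, 150, 120), c(12345, 99, 120), 2L,
                               cost = c(1 / 3, 2.5, NA)))
  paths <- write_drug_records(stats, emission_policy(), dir)
  back <- read_records(paths[["2"]])
  expect_identical(attr(back, "level"), "ingredient")
  expect_equal(back[key == "a|b"]$exact_exposure_count, 12345)
  expect_equal(back[key == "a|b"]$estimate_drug_combo_cost_per_day, 1 / 3)
  # the masked cell is a censored indicator with an upper bound, not a number
  expect_true(back[key == "a|c"]$exact_censored)
  expect_true(is.na(back[key == "a|c"]$exact_exposure_count))
  expect_equal(back[key == "a|c"]$censor_bound, 100)

  # write -> read -> write reproduces the file byte-identically
  dir2 <- withr::local_tempdir()
  write_drug_records(list("2" = back), emission_policy(), dir2)
  expect_identical(readLines(file.path(dir2, "db_drugs_2s.tsv")),
                   readLines(paths[["2"]]))
})

test_that("malformed and unknown inputs are rejected with context", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tsv")
  writeLines(c("drug_name_A\tatleast_exposure_count\tmystery_col",
               "a\t10\t1"), p)
  expect_error(read_records(p), "mystery_col")
  writeLines(c("drug_name_A\tatleast_exposure_count",
               "a\t10\textra"), p)
  expect_error(read_records(p), "line 2")
})

test_that("empty stats tables produce headered files with no rows", {
  dir <- withr::local_tempdir()
  empty <- mk_stats(character(), integer(), integer(), 2L)[0L]
  write_class_records(list("2" = empty), emission_policy(), dir)
  lines <- readLines(file.path(dir, "db_atc_classes_2s.tsv"))
  expect_identical(length(lines), 1L)
  expect_match(lines, "^atc_code_A\t")
})

test_that("the records README describes files and masking", {
  dir <- withr::local_tempdir()
  p <- write_records_readme(dir, emission_policy(), max_n = 2L)
  txt <- readLines(p)
  expect_true(any(grepl("db_drugs_2s.tsv", txt)))
  expect_true(any(grepl("'<100'", txt)))
})
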