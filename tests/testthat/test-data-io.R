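test_that("paired columns load into records by exact prefix", {
  path <- write_fixture_workbook(list(S1_Ax = c(0.8, 1.0), S1_My = c(0.2, 0.25)))
  rec <- load_measurements(path, "CTL")
  expect_equal(nrow(rec), 2L)
  expect_equal(unique(rec$sample_id), "S1")
  expect_equal(rec$axon_diameter, c(0.8, 1.0))
  expect_equal(rec$myelin_total, c(0.2, 0.25))
  expect_equal(rec$source_row, c(2L, 3L))
  expect_equal(unique(rec$group_label), "CTL")
})

test_that("a lone _Ax or _My column is a missing-counterpart error", {
  path <- write_fixture_workbook(list(S1_Ax = c(0.8, 1.0)))
  expect_error(load_measurements(path, "CTL"), "missing counterpart")
  path2 <- write_fixture_workbook(list(S1_My = c(0.8, 1.0)))
  expect_error(load_measurements(path2, "CTL"), "missing counterpart")
})

test_that("a workbook without paired columns is an empty-workbook error", {
  path <- write_fixture_workbook(list(other = 1:3))
  expect_error(load_measurements(path, "CTL"), "empty workbook")
})

test_that("prefix pairing is exact: Foo_Ax never pairs with FooBar_My", {
  path <- write_fixture_workbook(list(Foo_Ax = 1, FooBar_My = 2))
  expect_error(load_measurements(path, "CTL"), "missing counterpart")
})

test_that("suffix matching is case-sensitive", {
  path <- write_fixture_workbook(list(S1_Ax = 1, S1_My = 2, S2_ax = 1, S2_my = 2))
  rec <- load_measurements(path, "CTL")
  expect_equal(unique(rec$sample_id), "S1")
})

test_that("non-numeric and absent cells become missing records, not errors", {
  path <- write_fixture_workbook(list(S1_Ax = c("0.8", "", "oops"),
                                      S1_My = c("0.2", "0.3", "0.4")))
  rec <- load_measurements(path, "CTL")
  expect_equal(nrow(rec), 3L)
  expect_identical(is.na(rec$axon_diameter), c(FALSE, TRUE, TRUE))
  expect_equal(rec$myelin_total, c(0.2, 0.3, 0.4))
})

test_that("ragged sample columns keep the shorter column's tail as missing", {
  path <- write_fixture_workbook(list(S1_Ax = c(0.8, 0.9, 1.0),
                                      S1_My = c(0.2, 0.3)))
  rec <- load_measurements(path, "CTL")
  expect_equal(nrow(rec), 3L)
  expect_true(is.na(rec$myelin_total[3]))
})

test_that("one-sided myelin measurements are doubled at load", {
  path <- write_fixture_workbook(list(S1_Ax = 1.0, S1_My = 0.125))
  rec <- load_measurements(path, "CTL", myelin = "one-sided")
  expect_equal(rec$myelin_total, 0.25)
})

test_that("multiple samples across sheets load and pair independently", {
  path <- tempfile(fileext = ".xlsx")
  write_xlsx(list(
    a = tibble::tibble(S1_Ax = c(0.8, 0.9), S1_My = c(0.2, 0.2)),
    b = tibble::tibble(S2_Ax = 1.1, S2_My = 0.3)), path)
  rec <- load_measurements(path, "CTL")
  expect_equal(sort(unique(rec$sample_id)), c("S1", "S2"))
  expect_equal(nrow(rec), 3L)
})

test_that("write_outputs round-trips retained records and logs exclusions", {
  fib <- make_fibers(c(0.8, 1.0, 1.2), c(0.2, 0.25, 0.3))
  log <- make_records(c(0.1, 0.12), c(0.05, 0.06))
  log <- gratio:::make_exclusion_log(log, "axon_below_min")
  out <- tempfile()
  files <- write_outputs(fib, NULL, log, out)
  expect_true(all(file.exists(files)))
  back <- load_measurements(files[["cleaned_data"]], "CTL")
  expect_identical(back$axon_diameter, fib$axon_diameter)
  expect_identical(back$myelin_total, fib$myelin_total)
  exc <- readxl::read_excel(files[["exclusions"]])
  expect_equal(nrow(exc), 2L)
  expect_equal(unique(exc$reason), "axon_below_min")
})

test_that("an empty exclusion log still yields an exclusions sheet", {
  fib <- make_fibers(c(0.8, 1.0, 1.2), c(0.2, 0.25, 0.3))
  out <- tempfile()
  files <- write_outputs(fib, NULL, gratio:::empty_exclusion_log(), out)
  expect_length(files, 2L)
  exc <- readxl::read_excel(files[["exclusions"]])
  expect_equal(nrow(exc), 0L)
})
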