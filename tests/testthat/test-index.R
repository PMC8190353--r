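test_that("an index sheet is built from series headers, blanks never crash", {
  dirs <- list(withr::local_tempdir(), withr::local_tempdir(), withr::local_tempdir())
  params <- list(c(kvp = 120, st = 2.5), c(kvp = 100, st = 1.25), c(kvp = 120, st = 5))
  for (i in 1:3) {
    make_series(series_spec(series_id = paste0("IDX", i), n_slices = 2,
                            rows = 8, cols = 8, kvp = params[[i]]["kvp"],
                            slice_thickness = params[[i]]["st"]), dirs[[i]])
  }
  records <- lapply(dirs, read_series)
  sheet <- build_index(records)
  expect_equal(names(sheet), index_columns())
  expect_equal(nrow(sheet), 3)
  expect_equal(sheet$kVp, c(120, 100, 120))
  expect_equal(sheet$`Slice thickness`, c(2.5, 1.25, 5))
  expect_equal(sheet$`Image dimension`, rep("8,8", 3))
  expect_equal(sheet$`W, L`, rep("400,40", 3))
  expect_equal(sheet$`Image quality`, rep("", 3))  # blank until populated

  # a series lacking kVp gets a blank cell
  d4 <- withr::local_tempdir()
  make_series(series_spec(series_id = "NOKVP", n_slices = 2, rows = 8, cols = 8,
                          defects = list(defect("drop_tag", tag = "KVP"))), d4)
  s4 <- build_index(list(read_series(d4)))
  expect_true(is.na(s4$kVp))

  # empty input -> empty sheet with full header
  empty <- build_index(list())
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), index_columns())
})

test_that("filtering by parameter of interest matches the printed tabulation", {
  sheet <- table4_sheet()
  expect_equal(nrow(sheet), 18)
  expect_equal(nrow(filter_index(sheet, kVp = 120)), 18)
  expect_equal(nrow(filter_index(sheet, `Image quality` = "Bad")), 7)
  expect_equal(nrow(filter_index(sheet, where = "kVp=120; Image quality=Good")), 11)
  # tautology-equivalent: no predicates -> identity
  expect_equal(filter_index(sheet), sheet)
  expect_error(filter_index(sheet, Zodiac = "Leo"), class = "ctcurate_query_error")
  expect_error(filter_index(sheet, Zodiac = "Leo"), "Zodiac")
})

test_that("chained filters equal the conjunction filter", {
  sheet <- table4_sheet()
  chained <- filter_index(filter_index(sheet, `Image quality` = "Good"),
                          `Slice thickness` = 1.25)
  joint <- filter_index(sheet, `Image quality` = "Good", `Slice thickness` = 1.25)
  expect_equal(chained, joint)
  expect_equal(chained$SubjectID,
               sheet$SubjectID[sheet$`Image quality` == "Good" &
                                 sheet$`Slice thickness` == 1.25])
})

test_that("classification counts bins, routes leftovers to other, rejects overlaps", {
  sheet <- table4_sheet()
  cc <- classify_counts(sheet, "mA", list(`240` = 240, `200` = 200))
  expect_equal(cc$count[cc$bin == "240"], 3L)
  expect_equal(cc$count[cc$bin == "200"], 15L)
  expect_equal(cc$count[cc$bin == "other"], 0L)
  expect_equal(sum(cc$count), nrow(sheet))  # exhaustive bins sum to row count

  # range bins [lo, hi)
  cc <- classify_counts(sheet, "pixel spacing",
                        list(`0.6-0.7` = c(0.6, 0.7), `0.7-0.8` = c(0.7, 0.8)))
  expect_equal(cc$count[cc$bin == "0.6-0.7"],
               sum(sheet$`pixel spacing` >= 0.6 & sheet$`pixel spacing` < 0.7))
  expect_gt(cc$count[cc$bin == "other"], 0)

  expect_error(classify_counts(sheet, "mA", list(a = c(100, 250), b = 240)),
               class = "ctcurate_config_error")
  expect_error(classify_counts(sheet, "nope", list(1)),
               class = "ctcurate_query_error")

  empty <- build_index(list())
  cc <- classify_counts(empty, "kVp", list(`120` = 120, `100` = 100))
  expect_true(all(cc$count == 0))
})

test_that("the sheet round-trips through CSV cell-for-cell", {
  sheet <- table4_sheet()
  f <- withr::local_tempfile(fileext = ".csv")
  write_index(sheet, f)
  back <- read_index(f)
  expect_equal(as.data.frame(back), as.data.frame(ctcurate:::as_index_sheet(sheet)))
  # header is the exact fixed column order
  expect_equal(names(readr::read_csv(f, col_types = readr::cols(.default = "c"),
                                     n_max = 0)), index_columns())
})

test_that("manifest flags and validation verdicts populate the sheet", {
  dirs <- list(withr::local_tempdir(), withr::local_tempdir())
  for (i in 1:2) {
    make_series(series_spec(series_id = paste0("POP", i), n_slices = 2,
                            rows = 8, cols = 8), dirs[[i]])
  }
  sheet <- build_index(lapply(dirs, read_series),
                       subject_ids = c("POP1", "POP2"))
  manifest <- tibble::tibble(series_id = c("POP1", "POP2"),
                             quality_flag = c("good", "bad"),
                             discard_reason = c(NA, "metal_artifact"),
                             polyp = c(TRUE, FALSE))
  sheet <- index_add_manifest(sheet, manifest)
  expect_equal(sheet$`Image quality`, c("Good", "Bad"))
  expect_equal(sheet$`Metal artifact`, c("", "Yes"))
  expect_equal(sheet$`Polyp found`, c("Yes", "No"))
  sheet <- index_add_reports(sheet, tibble::tibble(series_id = "POP1",
                                                   verdict = "pass"))
  expect_equal(sheet$`DICOM validation`, c("pass", ""))
})
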