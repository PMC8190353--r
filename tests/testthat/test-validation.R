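test_that("element rules map presence/emptiness to the right finding codes", {
  dir <- clean_series_dir(n_slices = 2, id = "ELEM")
  inst <- read_dicom(file.path(dir, "slice_001.dcm"))
  reg <- default_registry()
  rule_for <- function(kw) reg[reg$keyword == kw, ]

  # type 1 present with value -> clean
  expect_equal(nrow(validate_element(rule_for("SeriesInstanceUID"), inst)), 0)
  # type 3 absent -> clean
  inst2 <- inst; inst2$elements[[tag_for("SliceLocation")]] <- NULL
  expect_equal(nrow(validate_element(rule_for("SliceLocation"), inst2)), 0)

  # type 1 absent / empty
  inst2 <- inst; inst2$elements[[tag_for("Rows")]] <- NULL
  f <- validate_element(rule_for("Rows"), inst2)
  expect_equal(f$code, "MISSING_TYPE1"); expect_equal(f$severity, "fail")
  inst2 <- inst
  inst2$elements[[tag_for("Modality")]]$value <- character(0)
  f <- validate_element(rule_for("Modality"), inst2)
  expect_equal(f$code, "EMPTY_TYPE1"); expect_equal(f$severity, "fail")

  # type 2 empty: fail under strict, warn under lenient
  inst2 <- inst
  inst2$elements[[tag_for("PatientID")]]$value <- character(0)
  f <- validate_element(rule_for("PatientID"), inst2, profile = "strict")
  expect_equal(f$code, "EMPTY_TYPE2"); expect_equal(f$severity, "fail")
  f <- validate_element(rule_for("PatientID"), inst2, profile = "lenient")
  expect_equal(f$severity, "warn")
  # type 2 absent fails either way
  inst2$elements[[tag_for("PatientID")]] <- NULL
  f <- validate_element(rule_for("PatientID"), inst2)
  expect_equal(f$code, "MISSING_TYPE2"); expect_equal(f$severity, "fail")

  # conditional rule: condition fires for CT, so absence is a failure
  inst2 <- inst; inst2$elements[[tag_for("PatientPosition")]] <- NULL
  f <- validate_element(rule_for("PatientPosition"), inst2)
  expect_equal(f$code, "MISSING_TYPE2")
  # condition does not fire -> no finding
  inst2$elements[[tag_for("Modality")]]$value <- "MR"
  expect_equal(nrow(validate_element(rule_for("PatientPosition"), inst2)), 0)
  # unset condition degrades to an info note
  r <- rule_for("PatientPosition"); r$condition <- NA_character_
  f <- validate_element(r, inst)
  expect_equal(f$severity, "info")
})

test_that("uniqueness checks catch varying series constants and duplicate SOP UIDs", {
  dir <- clean_series_dir(n_slices = 3, id = "UNIQ")
  s <- read_series(dir)
  expect_equal(nrow(check_uniqueness(s)), 0)

  s2 <- s
  s2$instances[[2]]$elements[[tag_for("KVP")]]$value <- 100
  f <- check_uniqueness(s2)
  expect_equal(f$code, "NON_UNIQUE")
  expect_equal(f$tag, tag_for("KVP"))

  s3 <- s
  s3$instances[[2]]$elements[[tag_for("SOPInstanceUID")]]$value <-
    dcm_value(s$instances[[1]], "SOPInstanceUID")
  f <- check_uniqueness(s3)
  expect_equal(f$code, "NON_UNIQUE")
  expect_equal(f$tag, tag_for("SOPInstanceUID"))

  # duplicated effective location is a warning-level note
  s4 <- s
  s4$instances[[2]]$elements[["0020,1041"]]$value <- 0
  f <- check_uniqueness(s4)
  expect_true("DUPLICATE_LOCATION" %in% f$code)
  expect_equal(f$severity[f$code == "DUPLICATE_LOCATION"], "warn")
})

test_that("gap detection infers spacing and counts missing slices", {
  r <- detect_missing_slices(c(0, 2.5, 5, 7.5))
  expect_false(r$indeterminate)
  expect_equal(r$inferred_spacing, 2.5)
  expect_equal(nrow(r$gaps), 0)

  r <- detect_missing_slices(c(0, 2.5, 7.5, 10))
  expect_equal(nrow(r$gaps), 1)
  expect_equal(r$gaps$location_before, 2.5)
  expect_equal(r$gaps$location_after, 7.5)
  expect_equal(r$gaps$estimated_missing, 1L)

  # a wider gap estimates more missing slices
  r <- detect_missing_slices(c(0, 2.5, 5, 15, 17.5, 20))
  expect_equal(r$gaps$estimated_missing, 3L)

  expect_true(detect_missing_slices(c(0))$indeterminate)
  expect_true(detect_missing_slices(numeric(0))$indeterminate)
  expect_error(detect_missing_slices(c(5, 0, 2.5)), class = "ctcurate_geometry_error")
})

test_that("a clean series passes strict validation with no fail findings", {
  dir <- clean_series_dir(n_slices = 4, id = "CLEAN")
  rep <- validate_series(dir)
  expect_equal(rep$verdict, "pass")
  expect_equal(sum(rep$findings$severity %in% c("fail", "warn")), 0)
  g <- glance(rep)
  expect_equal(g$n_fail, 0)
  expect_equal(g$verdict, "pass")
})

test_that("the verdict is fail exactly when a fail-severity finding exists", {
  dir <- withr::local_tempdir()
  make_series(series_spec(series_id = "V1", n_slices = 4, rows = 8, cols = 8,
                          defects = list(defect("empty_tag", tag = "PatientID"))),
              dir)
  strict <- validate_series(dir, profile = "strict")
  expect_equal(strict$verdict, "fail")
  expect_true(any(strict$findings$severity == "fail"))
  lenient <- validate_series(dir, profile = "lenient")
  expect_equal(lenient$verdict, "pass")
  expect_true(any(lenient$findings$code == "EMPTY_TYPE2"))
  expect_false(any(lenient$findings$severity == "fail"))
})

test_that("a removed mid-stack slice yields exactly one missing-slice gap", {
  dir <- withr::local_tempdir()
  make_series(series_spec(series_id = "GAP", n_slices = 6, rows = 8, cols = 8,
                          defects = list(defect("remove_slice", index = 3))), dir)
  rep <- validate_series(dir)
  expect_equal(rep$verdict, "fail")
  expect_equal(sum(rep$findings$code == "MISSING_SLICE"), 1)
  expect_equal(sum(rep$findings$severity == "fail"), 1)
})

test_that("validation reports are order independent", {
  dir <- clean_series_dir(n_slices = 5, id = "ORD")
  s <- read_series(dir)
  sh <- s
  set.seed(3)
  sh$instances <- s$instances[sample(5)]
  expect_equal(tidy(validate_series(s)), tidy(validate_series(sh)))
})

test_that("recognized vendor private tags yield info notes only", {
  dir <- withr::local_tempdir()
  make_series(series_spec(series_id = "PRIV", n_slices = 2, rows = 8, cols = 8,
                          private_tag = TRUE), dir)
  s <- read_series(dir)
  notes <- note_private_tags(s)
  expect_true(all(notes$code == "PRIVATE_TAG_NOTE"))
  expect_true(all(notes$severity == "info"))
  expect_gt(nrow(notes), 0)
  rep <- validate_series(dir)
  expect_equal(rep$verdict, "pass")

  # no private tags -> no notes; unregistered creator -> ignored
  dir2 <- clean_series_dir(n_slices = 2, id = "NOPRIV")
  expect_equal(nrow(note_private_tags(read_series(dir2))), 0)
  s2 <- read_series(dir2)
  s2$instances[[1]]$elements[["0019,0010"]] <-
    ctcurate:::new_element(0x0019, 0x0010, "LO", "ACME SCANNERS")
  expect_equal(nrow(note_private_tags(s2)), 0)
})

test_that("missing geometry on an instance is a finding, not a crash", {
  dir <- withr::local_tempdir()
  make_series(series_spec(
    series_id = "GEO", n_slices = 3, rows = 8, cols = 8,
    defects = list(defect("drop_tag", tag = "SliceLocation", index = 2),
                   defect("drop_tag", tag = "ImagePositionPatient", index = 2))),
    dir)
  rep <- validate_series(dir)
  expect_equal(rep$verdict, "fail")
  expect_true("MISSING_GEOMETRY" %in% rep$findings$code)
})

test_that("the registry round-trips through YAML and JSON and rejects bad configs", {
  reg <- default_registry()
  fy <- withr::local_tempfile(fileext = ".yaml")
  fj <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, fy)
  write_registry(reg, fj)
  expect_equal(as.data.frame(read_registry(fy)), as.data.frame(reg))
  expect_equal(as.data.frame(read_registry(fj)), as.data.frame(reg))

  bad <- reg
  bad$type_class[1] <- "9"
  expect_error(ctcurate:::check_registry(bad), class = "ctcurate_config_error")
  dup <- rbind(reg, reg[1, ])
  expect_error(ctcurate:::check_registry(dup), class = "ctcurate_config_error")

  # disabled modules (Clinical Trial, Contrast Bolus) contribute no findings
  f <- tidy(validate_series(clean_series_dir(2, id = "DIS")))
  expect_false(any(f$tag %in% c("0012,0010", "0012,0020", "0018,0010")))
})

test_that("reports serialize to JSON with stable keys", {
  dir <- clean_series_dir(n_slices = 2, id = "JSON")
  rep <- validate_series(dir)
  f <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$verdict, "pass")
  expect_equal(parsed$series_uid, rep$series_uid)
  expect_equal(names(parsed)[1:4],
               c("series_uid", "profile", "n_instances", "verdict"))
})
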