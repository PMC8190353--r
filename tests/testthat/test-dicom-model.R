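test_that("effective slice location prefers (0020,1041) and falls back to the position z", {
  dir <- clean_series_dir(n_slices = 2, id = "LOC")
  inst <- read_dicom(file.path(dir, "slice_001.dcm"))

  inst$elements[["0020,1041"]]$value <- -35.5
  expect_equal(effective_slice_location(inst), -35.5)

  # (0020,0032) is never consulted while (0020,1041) is present and non-empty
  inst$elements[["0020,0032"]]$value <- c(-200, -200, 999)
  expect_equal(effective_slice_location(inst), -35.5)

  inst$elements[["0020,1041"]] <- NULL
  inst$elements[["0020,0032"]]$value <- c(-200, -200, 42.5)
  expect_equal(effective_slice_location(inst), 42.5)

  # present-but-empty slice location also falls back
  inst$elements[["0020,1041"]] <- ctcurate:::new_element(0x0020, 0x1041, "DS", numeric(0))
  expect_equal(effective_slice_location(inst), 42.5)

  inst$elements[["0020,1041"]] <- NULL
  inst$elements[["0020,0032"]] <- NULL
  expect_error(effective_slice_location(inst), class = "ctcurate_missing_geometry")
})

test_that("non-axial orientations project the position onto the slice normal", {
  dir <- clean_series_dir(n_slices = 2, id = "OBL")
  inst <- read_dicom(file.path(dir, "slice_001.dcm"))
  inst$elements[["0020,1041"]] <- NULL
  # sagittal orientation: rows along +y, cols along +z => normal +x
  inst$elements[["0020,0037"]]$value <- c(0, 1, 0, 0, 0, 1)
  inst$elements[["0020,0032"]]$value <- c(5, 7, 9)
  expect_equal(effective_slice_location(inst), 5)
})

test_that("hierarchy grouping partitions instances exhaustively and disjointly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_series(series_spec(series_id = "A", n_slices = 6, rows = 8, cols = 8), d1)
  make_series(series_spec(series_id = "B", n_slices = 4, rows = 8, cols = 8), d2)
  insts <- c(lapply(sort(list.files(d1, full.names = TRUE)), read_dicom),
             lapply(sort(list.files(d2, full.names = TRUE)), read_dicom))
  grouped <- group_hierarchy(insts)
  expect_equal(nrow(grouped), 2)
  expect_setequal(grouped$n_instances, c(6, 4))
  expect_equal(sum(grouped$n_instances), length(insts))
  expect_length(attr(grouped, "unassignable"), 0)

  expect_equal(nrow(group_hierarchy(list())), 0)

  # two patients x two series each -> 4 records
  dirs <- replicate(4, withr::local_tempdir(.local_envir = parent.frame()))
  ids <- c("P1a", "P1b", "P2a", "P2b")
  pids <- c("P1", "P1", "P2", "P2")
  for (i in 1:4) {
    make_series(series_spec(series_id = ids[i], patient_id = pids[i],
                            n_slices = 2, rows = 8, cols = 8), dirs[i])
  }
  all_inst <- unlist(lapply(dirs, function(d) {
    lapply(sort(list.files(d, full.names = TRUE)), read_dicom)
  }), recursive = FALSE)
  g4 <- group_hierarchy(all_inst)
  expect_equal(nrow(g4), 4)
  expect_equal(sort(unique(g4$patient_id)), c("P1", "P2"))
})

test_that("instances missing every hierarchy key go to the unassignable bucket", {
  dir <- withr::local_tempdir()
  make_series(series_spec(
    series_id = "UNA", n_slices = 1, rows = 8, cols = 8,
    defects = list(defect("drop_tag", tag = "PatientID", index = 1),
                   defect("drop_tag", tag = "StudyInstanceUID", index = 1),
                   defect("drop_tag", tag = "SeriesInstanceUID", index = 1))), dir)
  g <- group_hierarchy(list(read_dicom(file.path(dir, "slice_001.dcm"))))
  expect_equal(nrow(g), 0)
  expect_length(attr(g, "unassignable"), 1)
})

test_that("sorting orders by location with deterministic tie-breaks", {
  dir <- clean_series_dir(n_slices = 4, id = "SRT")
  s <- read_series(dir)
  expect_equal(slice_locations(s), c(0, 2.5, 5, 7.5))

  # already sorted input is unchanged
  s2 <- sort_instances(s)
  expect_identical(lapply(s2$instances, function(x) dcm_value(x, "SOPInstanceUID")),
                   lapply(s$instances, function(x) dcm_value(x, "SOPInstanceUID")))

  # ties break by instance number ascending, and duplicates are noted
  s3 <- s
  s3$instances <- s$instances[1:2]
  s3$instances[[1]]$elements[["0020,1041"]]$value <- 2.5
  s3$instances[[1]]$elements[["0020,0032"]]$value <- c(-5, -5, 2.5)
  s3$instances[[1]]$elements[["0020,0013"]]$value <- 3
  s3$instances[[2]]$elements[["0020,0013"]]$value <- 2
  sorted <- sort_instances(s3)
  expect_equal(vapply(sorted$instances, function(x) dcm_value(x, "InstanceNumber"),
                      numeric(1)), c(2, 3))
  expect_gt(nrow(attr(sorted, "duplicate_locations")), 0)
})

test_that("sorting a shuffled series is permutation invariant", {
  dir <- clean_series_dir(n_slices = 8, id = "PRM")
  s <- read_series(dir)
  ref <- vapply(sort_instances(s)$instances,
                function(x) dcm_value(x, "SOPInstanceUID"), character(1))
  set.seed(11)
  for (i in 1:20) {
    sh <- s
    sh$instances <- s$instances[sample(length(s$instances))]
    got <- vapply(sort_instances(sh)$instances,
                  function(x) dcm_value(x, "SOPInstanceUID"), character(1))
    expect_identical(got, ref)
  }
})

test_that("sorting aborts with the offending SOP UID when geometry is missing", {
  dir <- withr::local_tempdir()
  make_series(series_spec(
    series_id = "NOGEO", n_slices = 3, rows = 8, cols = 8,
    defects = list(defect("drop_tag", tag = "SliceLocation", index = 2),
                   defect("drop_tag", tag = "ImagePositionPatient", index = 2))),
    dir)
  s <- read_series(dir)  # read_series tolerates the failed sort
  err <- tryCatch(sort_instances(s), error = function(e) e)
  expect_s3_class(err, "ctcurate_sort_error")
  expect_match(conditionMessage(err), "\\.3\\.")
})

test_that("series files with .ima extension are read too", {
  dir <- withr::local_tempdir()
  make_series(series_spec(series_id = "IMA", n_slices = 2, rows = 8, cols = 8,
                          ext = ".ima"), dir)
  s <- read_series(dir)
  expect_length(s$instances, 2)
  expect_equal(acquisition_params(s)$n_slices, 2)
})
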