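# Shared fixtures built in code at test time.

# A small clean series on disk; returns the directory.
clean_series_dir <- function(n_slices = 4, ..., id = "TST") {
  make_series(series_spec(series_id = id, n_slices = n_slices,
                          rows = 16, cols = 16, ...),
              withr::local_tempdir(.local_envir = parent.frame()))
}

# The 18-row printed excerpt of the curated-cohort tabulation, used for
# filter/query tests (all rows 120 kVp; 7 rows of bad diagnostic quality).
table4_sheet <- function() {
  rows <- tibble::tribble(
    ~SubjectID,        ~quality, ~polyp, ~st,  ~ma, ~ps,       ~age, ~sex,
    "SD VC 003M",      "Good",   "No",   2.5,  240, 0.703125,  40,   "M",
    "SD VC 006M",      "Good",   "Yes",  2.5,  240, 0.730469,  60,   "M",
    "SD VC 008M",      "Good",   "Yes",  2.5,  240, 0.681641,  50,   "M",
    "SD VC-197M",      "Bad",    "Yes",  2.5,  200, 0.650391,  50,   "F",
    "SD VC-396M",      "Good",   "Yes",  2.5,  200, 0.734375,  60,   "M",
    "SD VC-397M",      "Good",   "Yes",  1.25, 200, 0.796875,  70,   "M",
    "SD VC-401M",      "Good",   "Yes",  2.5,  200, 0.703125,  60,   "M",
    "WRAMC VC-001M",   "Good",   "Yes",  1.25, 200, 0.625,     50,   "M",
    "WRAMC VC-080M",   "Good",   "Yes",  1.25, 200, 0.664062,  50,   "M",
    "WRAMC VC-091M",   "Good",   "Yes",  1.25, 200, 0.78125,   70,   "M",
    "WRAMC VC-092M",   "Good",   "Yes",  1.25, 200, 0.78125,   50,   "M",
    "WRAMC VC-100M",   "Good",   "Yes",  1.25, 200, 0.664062,  60,   "M",
    "SD VC-394M",      "Bad",    "Yes",  2.5,  200, 0.689453,  60,   "F",
    "WRAMC VC-023M",   "Bad",    "",     1.25, 200, 0.683594,  60,   "M",
    "WRAMC VC-032M",   "Bad",    "Yes",  1.25, 200, 0.644531,  70,   "F",
    "WRAMC VC-050M",   "Bad",    "",     1.25, 200, 0.625,     50,   "F",
    "WRAMC VC-116M",   "Bad",    "",     1.25, 200, 0.625,     60,   "M",
    "WRAMC VC-117M",   "Bad",    "",     1.25, 200, 0.839844,  50,   "M"
  )
  sheet <- tibble::tibble(
    "SubjectID" = rows$SubjectID,
    "Image quality" = rows$quality,
    "Polyp found" = rows$polyp,
    "Slice thickness" = rows$st,
    "kVp" = 120,
    "mA" = rows$ma,
    "pixel spacing" = rows$ps,
    "Filter Kernel" = ifelse(grepl("^WRAMC", rows$SubjectID), "STANDARD", "SOFT"),
    "Image dimension" = "512,512",
    "W, L" = "400,40",
    "Age" = rows$age,
    "Gender" = rows$sex,
    "Study Date" = "2000"
  )
  ctcurate:::as_index_sheet(sheet)
}

# A series_record assembled in memory from a clean on-disk fixture, with a
# hook to edit instances before use.
edited_series <- function(dir, edit = identity) {
  s <- read_series(dir)
  s$instances <- lapply(s$instances, edit)
  s
}
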