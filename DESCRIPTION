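Package: ctcurate
Title: Systematic Curation of CT Colonography DICOM Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for systematic curation of CT imaging cohorts prior to
    image-analysis research, developed around the CT colonography use case.
    Provides a minimal DICOM Part-10 reader/writer for uncompressed
    explicit-VR little-endian CT slices, a declarative series validation
    framework (type-1/2 attribute rules, slice-location sorting with the
    Image Position (Patient) fallback, missing-slice gap detection,
    uniqueness checks), staged cohort quality filtering with flow reports,
    an acquisition-parameter index sheet with parameter-of-interest queries,
    proportional stratified sampling by largest remainder, z-linear volume
    reconstruction toward isotropic voxels, window/level and gamma display
    transforms, and a synthetic DICOM fixture generator that plants
    controlled defects for every validation finding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    png,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
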