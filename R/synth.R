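## Synthetic DICOM fixture generator: conformant CT series over the realistic
## acquisition-parameter space (slice thickness 1.25/2.5/5 mm, 100/120 kVp,
## 0.58-0.93 mm pixels, 16-bit planes), controlled defect planting for every
## validation finding, and cohort profiles that materialize the curated
## cohort compositions. Phantoms are deliberately simple (uniform HU, z-ramp,
## centered cylinder): enough to exercise geometry, interpolation and
## windowing, with no anatomical realism.

## Evaluate `expr` under `seed` and restore the caller's RNG state.
with_seed_restore <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Specify a synthetic CT series
#'
#' @param series_id Identifier; becomes PatientName/SubjectID and the series
#'   directory name.
#' @param n_slices Number of slices (>= 1).
#' @param slice_thickness Slice thickness and inter-slice spacing, mm.
#' @param z_start Location of the first slice, mm.
#' @param kvp,ma Tube voltage (kVp) and current (mA).
#' @param pixel_spacing In-plane pixel size, mm (square pixels).
#' @param rows,cols Matrix size.
#' @param patient_position One of FFS, FFP, HFS, HFP.
#' @param phantom `"z_ramp"` (HU affine in z), `"uniform"` (water), or
#'   `"cylinder"` (centered disc at +100 HU).
#' @param defects List of [defect()] specifications to plant.
#' @param seed Integer seed (reserved for randomized phantoms; the shipped
#'   phantoms are deterministic).
#' @param patient_id Patient identifier (defaults to `series_id`).
#' @param manufacturer,convolution_kernel,age,sex,study_date,description
#'   Header attributes.
#' @param window Display window as `c(width, level)` HU.
#' @param uid_seq Integer discriminator folded into generated UIDs.
#' @param private_tag Write a recognized vendor private block (creator
#'   "SIEMENS MED" in group 0019).
#' @param ext File extension for slice files (`".dcm"` or `".ima"`).
#' @return A `series_spec` list.
#' @export
series_spec <- function(series_id = "S001", n_slices = 4, slice_thickness = 2.5,
                        z_start = 0, kvp = 120, ma = 200,
                        pixel_spacing = 0.703125, rows = 32, cols = 32,
                        patient_position = "FFS",
                        phantom = c("z_ramp", "uniform", "cylinder"),
                        defects = list(), seed = 1L, patient_id = NULL,
                        manufacturer = "SIEMENS", convolution_kernel = "SOFT",
                        age = "060Y", sex = "M", study_date = "20000101",
                        description = "CTC supine", window = c(400, 40),
                        uid_seq = NULL, private_tag = FALSE, ext = ".dcm") {
  phantom <- match.arg(phantom)
  stopifnot(n_slices >= 1, slice_thickness > 0, pixel_spacing > 0,
            rows > 0, cols > 0)
  if (is.null(patient_id)) patient_id <- series_id
  if (is.null(uid_seq)) uid_seq <- sum(utf8ToInt(series_id))
  structure(
    list(series_id = series_id, n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness, z_start = z_start, kvp = kvp,
         ma = ma, pixel_spacing = pixel_spacing, rows = as.integer(rows),
         cols = as.integer(cols), patient_position = patient_position,
         phantom = phantom, defects = defects, seed = as.integer(seed),
         patient_id = patient_id, manufacturer = manufacturer,
         convolution_kernel = convolution_kernel, age = age, sex = sex,
         study_date = study_date, description = description, window = window,
         uid_seq = as.integer(uid_seq), private_tag = private_tag, ext = ext),
    class = "series_spec")
}

#' Specify a planted defect
#'
#' Each kind maps to exactly one expected validation outcome:
#' `drop_tag` of a type-1 tag -> `MISSING_TYPE1`; `empty_tag` of a type-2
#' tag -> `EMPTY_TYPE2`; `remove_slice` -> `MISSING_SLICE`;
#' `duplicate_sop_uid` -> `NON_UNIQUE`; `vary_series_constant` ->
#' `NON_UNIQUE`; `corrupt_file` -> `CORRUPT_FILE`; `drop_slice_location`
#' removes (0020,1041) everywhere and is expected to *pass* via the
#' (0020,0032) z-component fallback.
#'
#' @param kind One of `drop_tag`, `empty_tag`, `remove_slice`,
#'   `duplicate_sop_uid`, `vary_series_constant`, `drop_slice_location`,
#'   `corrupt_file`.
#' @param tag Target tag (keyword or `"GGGG,EEEE"`) where applicable.
#' @param index Target slice index; `NULL` targets a kind-specific default
#'   (all slices for `drop_slice_location`, slice 2 otherwise).
#' @param value Replacement value for `vary_series_constant`.
#' @return A `defect_spec` list.
#' @export
defect <- function(kind = c("drop_tag", "empty_tag", "remove_slice",
                            "duplicate_sop_uid", "vary_series_constant",
                            "drop_slice_location", "corrupt_file"),
                   tag = NULL, index = NULL, value = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, tag = tag, index = index, value = value),
            class = "defect_spec")
}

#' Expected finding code for each defect kind
#'
#' @param kind A defect kind (see [defect()]).
#' @return The finding code a strict validation is expected to raise, or
#'   `NA` for `drop_slice_location` (expected to pass via the fallback).
#' @export
expected_finding <- function(kind) {
  switch(kind,
         drop_tag = "MISSING_TYPE1",
         empty_tag = "EMPTY_TYPE2",
         remove_slice = "MISSING_SLICE",
         duplicate_sop_uid = "NON_UNIQUE",
         vary_series_constant = "NON_UNIQUE",
         corrupt_file = "CORRUPT_FILE",
         drop_slice_location = NA_character_,
         abort(sprintf("unknown defect kind '%s'", kind),
               class = "ctcurate_config_error"))
}

phantom_plane <- function(phantom, rows, cols, z) {
  ## stored values; RescaleIntercept -1024 puts the uniform phantom at 0 HU
  base <- matrix(1024L, nrow = rows, ncol = cols)
  if (phantom == "uniform") return(base)
  if (phantom == "z_ramp") return(base + as.integer(round(10 * z)))
  cy <- (row(base) - (rows + 1) / 2)^2 + (col(base) - (cols + 1) / 2)^2
  base + ifelse(cy <= (min(rows, cols) / 4)^2, 100L, 0L)
}

el_for <- function(keyword, value) {
  key <- tag_for(keyword)
  parts <- strsplit(key, ",", fixed = TRUE)[[1]]
  new_element(strtoi(parts[1], 16L), strtoi(parts[2], 16L), vr_for(key), value)
}

slice_elements <- function(spec, i) {
  z <- spec$z_start + (i - 1) * spec$slice_thickness
  half <- spec$pixel_spacing * spec$rows / 2
  els <- list(
    el_for("ImageType", c("ORIGINAL", "PRIMARY", "AXIAL")),
    el_for("SOPClassUID", .sop_class_ct),
    el_for("SOPInstanceUID", sprintf("%s.3.%d.%d", .uid_root, spec$uid_seq, i)),
    el_for("StudyDate", spec$study_date),
    el_for("StudyTime", "120000"),
    el_for("Modality", "CT"),
    el_for("Manufacturer", spec$manufacturer),
    el_for("SeriesDescription", spec$description),
    el_for("PatientName", spec$series_id),
    el_for("PatientID", spec$patient_id),
    el_for("PatientSex", spec$sex),
    el_for("PatientAge", spec$age),
    el_for("SliceThickness", spec$slice_thickness),
    el_for("KVP", spec$kvp),
    el_for("ExposureTime", 1000L),
    el_for("XRayTubeCurrent", spec$ma),
    el_for("ConvolutionKernel", spec$convolution_kernel),
    el_for("PatientPosition", spec$patient_position),
    el_for("StudyInstanceUID", sprintf("%s.1.%d", .uid_root, spec$uid_seq)),
    el_for("SeriesInstanceUID", sprintf("%s.2.%d", .uid_root, spec$uid_seq)),
    el_for("StudyID", "1"),
    el_for("SeriesNumber", 1L),
    el_for("InstanceNumber", i),
    el_for("ImagePositionPatient", c(-half, -half, z)),
    el_for("ImageOrientationPatient", c(1, 0, 0, 0, 1, 0)),
    el_for("SliceLocation", z),
    el_for("SamplesPerPixel", 1L),
    el_for("PhotometricInterpretation", "MONOCHROME2"),
    el_for("Rows", spec$rows),
    el_for("Columns", spec$cols),
    el_for("PixelSpacing", c(spec$pixel_spacing, spec$pixel_spacing)),
    el_for("BitsAllocated", 16L),
    el_for("BitsStored", 16L),
    el_for("HighBit", 15L),
    el_for("PixelRepresentation", 0L),
    el_for("WindowCenter", spec$window[2]),
    el_for("WindowWidth", spec$window[1]),
    el_for("RescaleIntercept", -1024),
    el_for("RescaleSlope", 1)
  )
  names(els) <- vapply(els, function(e) tag_key(e$group, e$element), character(1))
  if (isTRUE(spec$private_tag)) {
    els[["0019,0010"]] <- new_element(0x0019L, 0x0010L, "LO", "SIEMENS MED")
    els[["0019,1010"]] <- new_element(0x0019L, 0x1010L, "CS", "CTC")
  }
  els
}

empty_like <- function(el) {
  el$value <- if (is.numeric(el$value)) numeric(0) else character(0)
  el
}

#' Write a synthetic CT series to disk
#'
#' Writes `n_slices` DICOM Part-10 files (Explicit VR Little Endian) under
#' `dir`, fully populated for the default validation registry unless a
#' planted defect says otherwise. Phantom pixel planes are deterministic, so
#' equal specs produce byte-identical files.
#'
#' @param spec A [series_spec()].
#' @param dir Output directory for the slice files (created if needed).
#' @return `dir`, invisibly, with the spec attached as attribute `spec`.
#' @examples
#' d <- make_series(series_spec(n_slices = 3), tempfile())
#' validate_series(d)$verdict
#' @export
make_series <- function(spec, dir) {
  stopifnot(inherits(spec, "series_spec"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(sprintf("cannot create directory %s", dir), class = "ctcurate_io_error")
  }
  defects <- spec$defects
  kinds <- vapply(defects, function(d) d$kind, character(1))
  skip <- integer(0)
  for (d in defects[kinds == "remove_slice"]) {
    skip <- c(skip, d$index %||% ceiling(spec$n_slices / 2))
  }
  corrupt <- list()
  for (i in seq_len(spec$n_slices)) {
    if (i %in% skip) next
    els <- slice_elements(spec, i)
    for (d in defects) {
      key <- if (!is.null(d$tag)) as_tag_key(d$tag) else NULL
      target <- d$index %||% 2L
      if (d$kind == "drop_tag" && (is.null(d$index) || i == target)) {
        els[[key]] <- NULL
      } else if (d$kind == "empty_tag" && (is.null(d$index) || i == target)) {
        els[[key]] <- empty_like(els[[key]])
      } else if (d$kind == "drop_slice_location") {
        if (is.null(d$index) || i == d$index) els[["0020,1041"]] <- NULL
      } else if (d$kind == "vary_series_constant" && i == target) {
        vkey <- key %||% tag_for("KVP")
        els[[vkey]]$value <- d$value %||%
          (if (is.numeric(els[[vkey]]$value)) 100 else "ALTERED")
      } else if (d$kind == "duplicate_sop_uid" && i == target) {
        src <- max(1L, target - 1L)
        els[["0008,0018"]]$value <- sprintf("%s.3.%d.%d", .uid_root,
                                            spec$uid_seq, src)
      }
    }
    z <- spec$z_start + (i - 1) * spec$slice_thickness
    path <- file.path(dir, sprintf("slice_%03d%s", i, spec$ext))
    write_dicom(path, els,
                pixel = phantom_plane(spec$phantom, spec$rows, spec$cols, z))
    for (d in defects[kinds == "corrupt_file"]) {
      if (i == (d$index %||% 1L)) {
        bytes <- readBin(path, "raw", n = 80L)
        writeBin(bytes, path)
      }
    }
  }
  attr(dir, "spec") <- spec
  invisible(dir)
}

flow_profile_manifest <- function(seed) {
  n <- 187L
  roles <- c(rep("quality", 8), rep("artifact", 15), rep("invalid", 6),
             rep("clean", 158))
  q_reasons <- rep_len(quality_reasons(), 8)
  a_reasons <- rep_len(artifact_reasons(), 15)
  with_seed_restore(seed, {
    roles <- roles[sample.int(n)]
    polyp <- sample(c(rep(TRUE, 168), rep(FALSE, 19)))
    reason <- rep(NA_character_, n)
    reason[roles == "quality"] <- q_reasons
    reason[roles == "artifact"] <- a_reasons
    tibble::tibble(
      series_id = sprintf("S%03d", seq_len(n)),
      path = sprintf("S%03d", seq_len(n)),
      quality_flag = ifelse(roles == "quality", "bad", "good"),
      discard_reason = reason,
      role = roles,
      polyp = polyp
    )
  })
}

index_profile_manifest <- function(seed) {
  n <- 187L
  with_seed_restore(seed, {
    tibble::tibble(
      series_id = sprintf("S%03d", seq_len(n)),
      path = sprintf("S%03d", seq_len(n)),
      quality_flag = sample(c(rep("good", 166), rep("bad", 21))),
      discard_reason = NA_character_,
      role = "index",
      polyp = sample(c(rep(TRUE, 170), rep(FALSE, 17))),
      kvp = sample(c(rep(120, 185), rep(100, 2))),
      ma = sample(c(rep(240, 61), rep(200, 108), rep(140, 4), rep(300, 14))),
      slice_thickness = sample(c(rep(2.5, 130), rep(1, 57))),
      age = sample(c(rep("065Y", 43), rep("055Y", 80), rep("045Y", 56),
                     rep("075Y", 8))),
      pixel_spacing = sample(c(rep(0.546875, 23), rep(0.664062, 68),
                               rep(0.703125, 78), rep(0.839844, 17),
                               rep(0.95, 1)))
    )
  })
}

#' Materialize a synthetic cohort profile
#'
#' Writes a full synthetic cohort under `dir`: one DICOM series per entry
#' plus a `manifest.json`, deterministic for equal seeds.
#'
#' Two profiles are shipped. `"flow"` encodes the curated-cohort flow
#' composition: 187 series at intake, of which 8 are flagged bad diagnostic
#' quality, 15 carry artifact discard reasons (metal, motion, quantum
#' noise), and 6 are written with an empty type-2 PatientID so they fail
#' strict validation -- running [run_flow()] over it yields the
#' 187 / 179 / 164 / 158 stage counts. `"index"` encodes the per-column
#' attribute distributions of the curated index sheet (kVp 185/2 at 120/100,
#' mA 61/108/4 at 240/200/140, slice thickness 130/57 at 2.5/1 mm, quality
#' 166/21, age and pixel-size groups); the distributions are reproduced
#' column-by-column, with per-column "other" padding where the group counts
#' do not span all 187 series -- the groups are not a joint distribution.
#'
#' @param dir Output directory.
#' @param profile `"flow"` or `"index"`.
#' @param seed Integer seed driving entry shuffling.
#' @param n_slices,rows,cols Size of each synthetic series.
#' @return The cohort manifest tibble (also written to
#'   `<dir>/manifest.json`), with `dir` attached as attribute `dir`.
#' @export
make_cohort <- function(dir, profile = c("flow", "index"), seed = 1L,
                        n_slices = if (profile == "flow") 3L else 2L,
                        rows = 16L, cols = 16L) {
  profile <- match.arg(profile)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(sprintf("cannot create directory %s", dir), class = "ctcurate_io_error")
  }
  manifest <- if (profile == "flow") flow_profile_manifest(seed) else
    index_profile_manifest(seed)
  sts <- c(2.5, 2.5, 1.25, 5)
  pss <- c(0.703125, 0.664062, 0.78125, 0.625)
  pos <- c("FFS", "FFP")
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    defects <- list()
    if (profile == "flow" && m$role == "invalid") {
      defects <- list(defect("empty_tag", tag = "PatientID"))
    }
    spec <- series_spec(
      series_id = m$series_id,
      n_slices = n_slices,
      slice_thickness = if (profile == "index") m$slice_thickness else
        sts[(i - 1) %% length(sts) + 1],
      kvp = if (profile == "index") m$kvp else 120,
      ma = if (profile == "index") m$ma else 200,
      pixel_spacing = if (profile == "index") m$pixel_spacing else
        pss[(i - 1) %% length(pss) + 1],
      rows = rows, cols = cols,
      patient_position = pos[(i - 1) %% 2 + 1],
      phantom = "uniform",
      defects = defects,
      age = if (profile == "index") m$age else "060Y",
      sex = if (i %% 5 == 0) "F" else "M",
      uid_seq = i
    )
    make_series(spec, file.path(dir, m$series_id))
  }
  write_manifest(manifest, file.path(dir, "manifest.json"))
  attr(manifest, "dir") <- dir
  manifest
}
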