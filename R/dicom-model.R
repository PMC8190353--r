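## Patient -> Study -> Series -> Image data model. A series_record is a light
## S3 record; collection-level views are tibbles.

new_series_record <- function(patient_id, study_uid, series_uid, instances,
                              source = NA_character_) {
  structure(
    list(patient_id = patient_id, study_uid = study_uid,
         series_uid = series_uid, instances = instances, source = source),
    class = "series_record"
  )
}

#' @export
print.series_record <- function(x, ...) {
  cat(sprintf("<series_record> %s\n  patient %s, study %s\n  %d instance(s)\n",
              x$series_uid, x$patient_id, x$study_uid, length(x$instances)))
  invisible(x)
}

#' Effective slice location of a CT instance
#'
#' CT archives store the slice position redundantly: Slice Location
#' (0020,1041) when present is used directly; otherwise the location is
#' derived from Image Position (Patient) (0020,0032). For axial scans that is
#' its z component; when Image Orientation (Patient) (0020,0037) is present
#' the position is projected onto the slice normal (the cross product of the
#' row and column direction cosines), which degenerates to z for axial
#' orientations and keeps ordering meaningful for oblique ones.
#'
#' @param inst A `dicom_instance`.
#' @return Slice location in mm.
#' @section Errors: when both tags are absent (or empty) a condition of class
#'   `ctcurate_missing_geometry` is signalled; the series validator records
#'   this as a finding instead of failing.
#' @export
effective_slice_location <- function(inst) {
  sl <- dcm_value(inst, "SliceLocation")
  if (!is.null(sl) && length(sl) >= 1 && is.finite(sl[1])) {
    return(as.numeric(sl[1]))
  }
  ipp <- dcm_value(inst, "ImagePositionPatient")
  if (!is.null(ipp) && length(ipp) == 3 && all(is.finite(ipp))) {
    iop <- dcm_value(inst, "ImageOrientationPatient")
    if (!is.null(iop) && length(iop) == 6 && all(is.finite(iop))) {
      r <- iop[1:3]; cc <- iop[4:6]
      normal <- c(r[2] * cc[3] - r[3] * cc[2],
                  r[3] * cc[1] - r[1] * cc[3],
                  r[1] * cc[2] - r[2] * cc[1])
      return(sum(as.numeric(ipp) * normal))
    }
    return(as.numeric(ipp[3]))
  }
  abort(
    sprintf("instance %s: both (0020,1041) and (0020,0032) are absent or empty",
            dcm_chr1(inst, "SOPInstanceUID") %||% "<no SOP UID>"),
    class = "ctcurate_missing_geometry"
  )
}

#' Group loose instances into series records
#'
#' Partitions instances by the Patient -> Study -> Series hierarchy keys
#' (PatientID, StudyInstanceUID, SeriesInstanceUID). The partition is
#' exhaustive and disjoint; instances missing all three keys are routed to an
#' "unassignable" bucket reported via an attribute.
#'
#' @param instances A list of `dicom_instance` objects.
#' @return A tibble with one row per series: `patient_id`, `study_uid`,
#'   `series_uid`, `n_instances` and a `record` list-column of
#'   `series_record` objects. Attribute `unassignable` holds instances
#'   carrying none of the three keys.
#' @export
group_hierarchy <- function(instances) {
  keys <- purrr::map(instances, function(inst) {
    c(patient = dcm_chr1(inst, "PatientID"),
      study = dcm_chr1(inst, "StudyInstanceUID"),
      series = dcm_chr1(inst, "SeriesInstanceUID"))
  })
  unassignable <- purrr::map_lgl(keys, function(k) all(is.na(k)))
  assigned <- instances[!unassignable]
  keys <- keys[!unassignable]
  if (length(assigned) == 0) {
    out <- tibble::tibble(patient_id = character(), study_uid = character(),
                          series_uid = character(), n_instances = integer(),
                          record = list())
    attr(out, "unassignable") <- instances[unassignable]
    return(out)
  }
  key_str <- vapply(keys, function(k) paste(k, collapse = "\r"), character(1))
  groups <- split(seq_along(assigned), key_str)
  rows <- purrr::map(names(groups), function(ks) {
    parts <- strsplit(ks, "\r", fixed = TRUE)[[1]]
    idx <- groups[[ks]]
    tibble::tibble(
      patient_id = parts[1], study_uid = parts[2], series_uid = parts[3],
      n_instances = length(idx),
      record = list(new_series_record(parts[1], parts[2], parts[3],
                                      assigned[idx]))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id,
                        .data$study_uid, .data$series_uid)
  attr(out, "unassignable") <- instances[unassignable]
  out
}

## DICOM files in a directory: *.dcm, *.ima, or extension-less files that
## carry the DICM magic.
list_dicom_files <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  ext <- tolower(tools::file_ext(files))
  candidate <- ext %in% c("dcm", "ima") | ext == ""
  files[candidate]
}

#' Read one directory as a single CT series
#'
#' Reads every DICOM file in `dir` (`.dcm`, `.ima`, or extension-less with the
#' `DICM` magic) into one `series_record`, following the
#' one-directory-one-series layout the fixture generator writes. Hierarchy
#' keys are taken from the first instance that carries them. Use
#' [group_hierarchy()] for mixed collections.
#'
#' @param dir Directory of slice files.
#' @param on_error `"abort"` (default) to fail on the first unreadable file,
#'   or `"collect"` to keep going and report failures via the
#'   `read_errors` attribute (a tibble of `path`, `message`) -- this is what
#'   the validator uses so that a corrupt file becomes a finding.
#' @return A `series_record`, sorted by effective slice location when every
#'   instance yields one (left unsorted otherwise; validation reports the
#'   missing geometry).
#' @export
read_series <- function(dir, on_error = c("abort", "collect")) {
  on_error <- match.arg(on_error)
  if (!dir.exists(dir)) {
    abort(sprintf("no such directory: %s", dir), class = "ctcurate_io_error")
  }
  files <- sort(list_dicom_files(dir))
  instances <- list()
  errors <- list()
  for (f in files) {
    res <- tryCatch(read_dicom(f), error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort") stop(res)
      errors[[length(errors) + 1L]] <-
        tibble::tibble(path = f, message = conditionMessage(res))
    } else {
      instances[[length(instances) + 1L]] <- res
    }
  }
  first_chr <- function(tag) {
    for (inst in instances) {
      v <- dcm_chr1(inst, tag)
      if (!is.na(v)) return(v)
    }
    NA_character_
  }
  rec <- new_series_record(first_chr("PatientID"), first_chr("StudyInstanceUID"),
                           first_chr("SeriesInstanceUID"), instances,
                           source = dir)
  rec <- tryCatch(sort_instances(rec),
                  ctcurate_missing_geometry = function(e) rec,
                  ctcurate_sort_error = function(e) rec)
  attr(rec, "read_errors") <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(path = character(), message = character())
  rec
}

#' Sort the instances of a series by effective slice location
#'
#' Orders ascending by [effective_slice_location()]; ties (within 1e-3 mm)
#' break by Instance Number ascending, then SOP Instance UID lexicographic,
#' so the ordering is a deterministic permutation of the input. Locations
#' duplicated within tolerance are noted via the `duplicate_locations`
#' attribute (the validator turns them into findings).
#'
#' @param series A `series_record`.
#' @return The series with instances reordered.
#' @section Errors: if any instance yields no effective location, a
#'   `ctcurate_sort_error` is signalled listing the offending SOP UIDs.
#' @export
sort_instances <- function(series) {
  insts <- series$instances
  if (length(insts) == 0) return(series)
  locs <- rep(NA_real_, length(insts))
  bad <- character(0)
  for (i in seq_along(insts)) {
    loc <- tryCatch(effective_slice_location(insts[[i]]),
                    ctcurate_missing_geometry = function(e) NA_real_)
    if (is.na(loc)) {
      bad <- c(bad, dcm_chr1(insts[[i]], "SOPInstanceUID") %||% "<no SOP UID>")
    }
    locs[i] <- loc
  }
  if (length(bad)) {
    abort(paste0("cannot sort: no effective slice location for instance(s) ",
                 paste(bad, collapse = ", ")),
          class = "ctcurate_sort_error", sop_uids = bad)
  }
  inum <- vapply(insts, function(x) {
    v <- dcm_num1(x, "InstanceNumber"); if (is.na(v)) Inf else v
  }, numeric(1))
  sop <- vapply(insts, function(x) dcm_chr1(x, "SOPInstanceUID") %||% "",
                character(1))
  ## quantize locations so sub-tolerance jitter does not perturb the order
  qloc <- round(locs / .loc_tol)
  ord <- order(qloc, inum, sop)
  series$instances <- insts[ord]
  qs <- qloc[ord]
  dup <- duplicated(qs) | duplicated(qs, fromLast = TRUE)
  dup_tbl <- tibble::tibble(location = locs[ord][dup], sop_instance_uid = sop[ord][dup])
  attr(series, "locations") <- locs[ord]
  attr(series, "duplicate_locations") <- dup_tbl
  series
}

#' Effective slice locations of a (sorted) series
#'
#' @param series A `series_record`.
#' @return Numeric vector of locations in mm, one per instance.
#' @export
slice_locations <- function(series) {
  vapply(series$instances, effective_slice_location, numeric(1))
}

#' Summarize the acquisition parameters of a series
#'
#' Reads the acquisition attributes the curation index cares about (slice
#' thickness, kVp, mA, pixel spacing, kernel, position, manufacturer, matrix
#' size) from the series headers.
#'
#' @param series A `series_record`.
#' @return A one-row tibble.
#' @export
acquisition_params <- function(series) {
  inst <- series$instances[[1]]
  ps <- dcm_value(inst, "PixelSpacing")
  tibble::tibble(
    slice_thickness = dcm_num1(inst, "SliceThickness"),
    kvp = dcm_num1(inst, "KVP"),
    ma = dcm_num1(inst, "XRayTubeCurrent"),
    pixel_spacing_row = if (length(ps) >= 1) as.numeric(ps[1]) else NA_real_,
    pixel_spacing_col = if (length(ps) >= 2) as.numeric(ps[2]) else NA_real_,
    convolution_kernel = dcm_chr1(inst, "ConvolutionKernel"),
    patient_position = dcm_chr1(inst, "PatientPosition"),
    manufacturer = dcm_chr1(inst, "Manufacturer"),
    rows = as.integer(dcm_num1(inst, "Rows")),
    cols = as.integer(dcm_num1(inst, "Columns")),
    n_slices = length(series$instances)
  )
}
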