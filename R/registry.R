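## Declarative validation registry: which attributes each DICOM CT module
## requires, at which type class, and at which uniqueness scope.

.registry_cols <- c("module", "keyword", "tag", "type_class", "uniqueness",
                    "condition", "note_presence", "enabled")

registry_row <- function(module, keyword, type_class, uniqueness = "none",
                         condition = NA_character_, note_presence = FALSE,
                         enabled = TRUE) {
  tibble::tibble(module = module, keyword = keyword, tag = tag_for(keyword),
                 type_class = type_class, uniqueness = uniqueness,
                 condition = condition, note_presence = note_presence,
                 enabled = enabled)
}

#' Default CT validation registry
#'
#' The shipped rule set covers the CT information-object modules a curation
#' pipeline screens: Patient, General Study, General Series, General
#' Equipment, General Image, Image Plane, Image Pixel, CT Image, CT
#' acquisition and SOP Common. Clinical Trial and Contrast Bolus rules are
#' present but disabled by default: anonymized archives have those modules
#' stripped, so validating them would fail every series.
#'
#' Type classes follow the DICOM requirement classes: type 1 must be present
#' and non-empty, type 2 present (possibly empty), type 3 optional; `1C`/`2C`
#' apply only when their registered condition holds. Uniqueness scopes:
#' `series` = one value across the series (series UID, slice thickness, kVp,
#' patient position, ...), `instance` = distinct per instance (SOP UID).
#'
#' @return A tibble with columns `module`, `keyword`, `tag`, `type_class`
#'   (`"1"`, `"1C"`, `"2"`, `"2C"`, `"3"`), `uniqueness` (`"none"`,
#'   `"series"`, `"instance"`), `condition` (name of a registered condition
#'   predicate or `NA`), `note_presence` (emit an info note when a type-3 tag
#'   is present), `enabled`.
#' @seealso [validate_series()], [read_registry()]
#' @export
default_registry <- function() {
  if (is.null(.pkg_cache$registry)) .pkg_cache$registry <- build_default_registry()
  .pkg_cache$registry
}

.pkg_cache <- new.env(parent = emptyenv())

build_default_registry <- function() {
  dplyr::bind_rows(
    registry_row("Patient", "PatientName", "2"),
    registry_row("Patient", "PatientID", "2", uniqueness = "series"),
    registry_row("General Study", "StudyInstanceUID", "1", uniqueness = "series"),
    registry_row("General Study", "StudyDate", "2"),
    registry_row("General Series", "Modality", "1", uniqueness = "series"),
    registry_row("General Series", "SeriesInstanceUID", "1", uniqueness = "series"),
    registry_row("General Series", "SeriesNumber", "2"),
    registry_row("General Series", "PatientPosition", "2C",
                 uniqueness = "series", condition = "modality_is_ct"),
    registry_row("General Equipment", "Manufacturer", "2", uniqueness = "series"),
    registry_row("General Image", "InstanceNumber", "2"),
    registry_row("Image Plane", "PixelSpacing", "1", uniqueness = "series"),
    registry_row("Image Plane", "ImageOrientationPatient", "1"),
    registry_row("Image Plane", "ImagePositionPatient", "1"),
    registry_row("Image Plane", "SliceThickness", "2", uniqueness = "series"),
    registry_row("Image Plane", "SliceLocation", "3"),
    registry_row("Image Pixel", "SamplesPerPixel", "1"),
    registry_row("Image Pixel", "PhotometricInterpretation", "1"),
    registry_row("Image Pixel", "Rows", "1", uniqueness = "series"),
    registry_row("Image Pixel", "Columns", "1", uniqueness = "series"),
    registry_row("Image Pixel", "BitsAllocated", "1"),
    registry_row("Image Pixel", "BitsStored", "1"),
    registry_row("Image Pixel", "HighBit", "1"),
    registry_row("Image Pixel", "PixelRepresentation", "1"),
    registry_row("CT Image", "ImageType", "1"),
    registry_row("CT Image", "KVP", "2", uniqueness = "series"),
    registry_row("CT Image", "RescaleIntercept", "1"),
    registry_row("CT Image", "RescaleSlope", "1"),
    registry_row("CT acquisition", "ConvolutionKernel", "3", note_presence = TRUE),
    registry_row("CT acquisition", "ExposureTime", "3", note_presence = TRUE),
    registry_row("CT acquisition", "XRayTubeCurrent", "3"),
    registry_row("SOP Common", "SOPClassUID", "1"),
    registry_row("SOP Common", "SOPInstanceUID", "1", uniqueness = "instance"),
    registry_row("Clinical Trial", "ClinicalTrialSponsorName", "2", enabled = FALSE),
    registry_row("Clinical Trial", "ClinicalTrialProtocolID", "2", enabled = FALSE),
    registry_row("Contrast Bolus", "ContrastBolusAgent", "2", enabled = FALSE)
  )
}

## Named predicates a 1C/2C rule's `condition` column can reference. A rule
## whose condition is NA or unregistered degrades to an info note rather than
## guessing.
.registry_conditions <- list(
  modality_is_ct = function(inst) identical(dcm_chr1(inst, "Modality"), "CT"),
  always = function(inst) TRUE
)

#' Read or write a validation registry file
#'
#' Registries serialize to YAML or JSON (by file extension) with one mapping
#' per rule mirroring the registry columns, so a site can override the
#' shipped defaults without touching code.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param registry A registry tibble (see [default_registry()]).
#' @return `read_registry()` returns a registry tibble; `write_registry()`
#'   returns `path` invisibly.
#' @export
read_registry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    abort(sprintf("unsupported registry format '.%s'", ext),
          class = "ctcurate_config_error")
  }
  rows <- purrr::map(raw, function(r) {
    registry_row(
      module = r$module, keyword = r$keyword,
      type_class = as.character(r$type_class),
      uniqueness = r$uniqueness %||% "none",
      condition = r$condition %||% NA_character_,
      note_presence = isTRUE(r$note_presence),
      enabled = !isFALSE(r$enabled)
    )
  })
  out <- dplyr::bind_rows(rows)
  check_registry(out)
  out
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  check_registry(registry)
  recs <- purrr::pmap(registry, function(module, keyword, tag, type_class,
                                         uniqueness, condition, note_presence,
                                         enabled) {
    r <- list(module = module, keyword = keyword, type_class = type_class,
              uniqueness = uniqueness, note_presence = note_presence,
              enabled = enabled)
    if (!is.na(condition)) r$condition <- condition
    r
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(recs, path)
  } else if (ext == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    abort(sprintf("unsupported registry format '.%s'", ext),
          class = "ctcurate_config_error")
  }
  invisible(path)
}

check_registry <- function(registry) {
  if (!all(.registry_cols %in% names(registry))) {
    abort("registry is missing required columns", class = "ctcurate_config_error")
  }
  if (!all(registry$type_class %in% c("1", "1C", "2", "2C", "3"))) {
    abort("registry type_class must be one of 1, 1C, 2, 2C, 3",
          class = "ctcurate_config_error")
  }
  dup <- registry |>
    dplyr::count(.data$module, .data$tag) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("tag %s appears twice within module %s",
                  dup$tag[1], dup$module[1]),
          class = "ctcurate_config_error")
  }
  invisible(registry)
}

#' Default vendor private-tag registry
#'
#' Maps private-creator identifiers to vendor labels. Recognized private
#' blocks produce informational findings (presence and VR only); unknown
#' private creators are ignored. Never affects the verdict.
#'
#' @return A tibble with columns `creator`, `vendor`.
#' @export
default_vendor_registry <- function() {
  tibble::tibble(
    creator = c("SIEMENS MED", "SIEMENS CT VA0  COAD", "GEMS_IDEN_01",
                "Philips Imaging DD 001", "TOSHIBA_MEC_CT3"),
    vendor = c("Siemens", "Siemens", "GE", "Philips", "Toshiba")
  )
}
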