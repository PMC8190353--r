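## Attribute-based classification: one index-sheet row per series, queryable
## by parameter of interest. The sheet is plain CSV (UTF-8, header row,
## quoted text) so it is diff-able and spreadsheet-openable.

#' Column header of the acquisition index sheet
#'
#' The fixed, ordered column set of the per-series tabulation used to select
#' datasets by parameter of interest during empirical testing.
#'
#' @return Character vector of column names.
#' @export
index_columns <- function() {
  c("SubjectID", "Patient ID", "Image quality", "DICOM validation",
    "Metal artifact", "Polyp found", "Slice thickness", "kVp", "mA",
    "Contrast", "pixel spacing", "Filter Kernel", "Image dimension", "W, L",
    "Patient position", "Slices", "Colon segment", "Age", "Gender",
    "Manufacturer", "Description", "Study Date")
}

.index_numeric_cols <- c("Slice thickness", "kVp", "mA", "pixel spacing", "Age")

empty_index <- function() {
  cols <- index_columns()
  out <- tibble::as_tibble(setNames(
    lapply(cols, function(cl) {
      if (cl %in% .index_numeric_cols) numeric(0) else character(0)
    }), cols))
  class(out) <- c("index_sheet", class(out))
  out
}

as_index_sheet <- function(x) {
  missing_cols <- setdiff(index_columns(), names(x))
  for (cl in missing_cols) {
    x[[cl]] <- if (cl %in% .index_numeric_cols) NA_real_ else NA_character_
  }
  x <- x[, index_columns(), drop = FALSE]
  for (cl in .index_numeric_cols) x[[cl]] <- as.numeric(x[[cl]])
  for (cl in setdiff(index_columns(), .index_numeric_cols)) {
    x[[cl]] <- as.character(x[[cl]])
  }
  ## blank cells in text columns are empty strings, not NA sentinels
  for (cl in setdiff(index_columns(), .index_numeric_cols)) {
    x[[cl]][is.na(x[[cl]])] <- ""
  }
  x <- tibble::as_tibble(x)
  if (!inherits(x, "index_sheet")) class(x) <- c("index_sheet", class(x))
  x
}

## Parse "060Y" / "60" style age strings into years.
parse_age <- function(x) {
  if (is.na(x)) return(NA_real_)
  suppressWarnings(as.numeric(sub("^0*([0-9]+)[DWMY]?$", "\\1", x)))
}

index_row_from_series <- function(series) {
  inst <- series$instances[[1]]
  ap <- acquisition_params(series)
  w <- dcm_num1(inst, "WindowWidth")
  l <- dcm_num1(inst, "WindowCenter")
  tibble::tibble(
    "SubjectID" = dcm_chr1(inst, "PatientName") %||% NA_character_,
    "Patient ID" = series$patient_id %||% NA_character_,
    "Image quality" = NA_character_,
    "DICOM validation" = NA_character_,
    "Metal artifact" = NA_character_,
    "Polyp found" = NA_character_,
    "Slice thickness" = ap$slice_thickness,
    "kVp" = ap$kvp,
    "mA" = ap$ma,
    "Contrast" = dcm_chr1(inst, "ContrastBolusAgent"),
    "pixel spacing" = ap$pixel_spacing_row,
    "Filter Kernel" = ap$convolution_kernel,
    "Image dimension" = if (is.na(ap$rows)) NA_character_ else
      paste0(ap$rows, ",", ap$cols),
    "W, L" = if (is.na(w) || is.na(l)) NA_character_ else paste0(w, ",", l),
    "Patient position" = ap$patient_position,
    "Slices" = as.character(ap$n_slices),
    "Colon segment" = NA_character_,
    "Age" = parse_age(dcm_chr1(inst, "PatientAge")),
    "Gender" = dcm_chr1(inst, "PatientSex"),
    "Manufacturer" = ap$manufacturer,
    "Description" = dcm_chr1(inst, "SeriesDescription"),
    "Study Date" = dcm_chr1(inst, "StudyDate")
  )
}

#' Build an acquisition index sheet from series records
#'
#' One row per series, attributes copied from the DICOM headers. Missing
#' attributes become blank cells, never an error. Quality/validation columns
#' are blank until populated from a manifest and validation reports (see
#' [index_add_manifest()] and [index_add_reports()]).
#'
#' @param records A list of `series_record` objects (or a single one), or
#'   the tibble returned by [group_hierarchy()].
#' @param subject_ids Optional character vector overriding the `SubjectID`
#'   column (defaults to PatientName from the headers).
#' @return An `index_sheet` tibble with exactly the [index_columns()]
#'   columns.
#' @export
build_index <- function(records, subject_ids = NULL) {
  if (inherits(records, "series_record")) records <- list(records)
  if (is.data.frame(records) && "record" %in% names(records)) {
    records <- records$record
  }
  if (length(records) == 0) return(empty_index())
  rows <- dplyr::bind_rows(purrr::map(records, index_row_from_series))
  if (!is.null(subject_ids)) {
    stopifnot(length(subject_ids) == nrow(rows))
    rows$SubjectID <- subject_ids
  }
  if (anyDuplicated(stats::na.omit(rows$SubjectID))) {
    warn("SubjectID values are not unique within the sheet")
  }
  as_index_sheet(rows)
}

#' Populate index columns from a cohort manifest
#'
#' Joins manifest flags onto the sheet by `SubjectID` = `series_id`: image
#' quality (`Good`/`Bad`), metal-artifact flag, and polyp flag when the
#' manifest carries them.
#'
#' @param sheet An `index_sheet`.
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @return The updated sheet.
#' @export
index_add_manifest <- function(sheet, manifest) {
  i <- match(sheet$SubjectID, manifest$series_id)
  hit <- !is.na(i)
  sheet$`Image quality`[hit] <-
    ifelse(manifest$quality_flag[i[hit]] == "good", "Good", "Bad")
  if ("discard_reason" %in% names(manifest)) {
    sheet$`Metal artifact`[hit] <-
      ifelse(!is.na(manifest$discard_reason[i[hit]]) &
               manifest$discard_reason[i[hit]] == "metal_artifact", "Yes", "")
  }
  if ("polyp" %in% names(manifest)) {
    sheet$`Polyp found`[hit] <- ifelse(manifest$polyp[i[hit]], "Yes", "No")
  }
  sheet
}

#' Populate the validation column from validation reports
#'
#' @param sheet An `index_sheet`.
#' @param verdicts Tibble with `series_id` and `verdict` (e.g. the
#'   `verdicts` field of a [run_flow()] report), matched on `SubjectID`.
#' @return The updated sheet.
#' @export
index_add_reports <- function(sheet, verdicts) {
  i <- match(sheet$SubjectID, verdicts$series_id)
  hit <- !is.na(i)
  sheet$`DICOM validation`[hit] <- verdicts$verdict[i[hit]]
  sheet
}

check_columns <- function(sheet, cols) {
  unknown <- setdiff(cols, names(sheet))
  if (length(unknown)) {
    abort(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")),
          class = "ctcurate_query_error")
  }
}

#' Filter an index sheet by parameter of interest
#'
#' Keeps rows satisfying the conjunction of column predicates, preserving
#' the original row order. Predicates are given as named arguments
#' (`kVp = 120` keeps rows whose `kVp` equals 120; numeric comparison uses a
#' 1e-9 tolerance) and/or as a query string like `"kVp=120; Image quality=Good"`.
#'
#' @param sheet An `index_sheet`.
#' @param ... Named equality predicates; names must be sheet columns.
#' @param where Optional query string, `"col=value"` terms joined by `;`.
#' @return The filtered `index_sheet`.
#' @examples
#' sheet <- build_index(list())
#' filter_index(sheet, kVp = 120)
#' @export
filter_index <- function(sheet, ..., where = NULL) {
  preds <- list(...)
  if (!is.null(where)) {
    terms <- strsplit(where, ";", fixed = TRUE)[[1]]
    for (term in terms) {
      kv <- strsplit(term, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        abort(sprintf("cannot parse query term '%s'", term),
              class = "ctcurate_query_error")
      }
      preds[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  if (length(preds) == 0) return(sheet)
  if (is.null(names(preds)) || any(names(preds) == "")) {
    abort("all predicates must be named with a column", class = "ctcurate_query_error")
  }
  check_columns(sheet, names(preds))
  keep <- rep(TRUE, nrow(sheet))
  for (col in names(preds)) {
    want <- preds[[col]]
    have <- sheet[[col]]
    if (is.numeric(have)) {
      want <- suppressWarnings(as.numeric(want))
      keep <- keep & !is.na(have) & abs(have - want) < 1e-9
    } else {
      keep <- keep & !is.na(have) & have == as.character(want)
    }
  }
  sheet[keep, , drop = FALSE]
}

bin_matches <- function(values, bin) {
  if (is.numeric(values)) {
    bin <- suppressWarnings(as.numeric(bin))
    if (length(bin) == 2) {
      !is.na(values) & values >= bin[1] & values < bin[2]
    } else {
      !is.na(values) & abs(values - bin[1]) < 1e-6
    }
  } else {
    !is.na(values) & values == as.character(bin[1])
  }
}

#' Count index rows per bin of one column
#'
#' Bins are scalars (exact match; 1e-6 tolerance for numerics) or length-2
#' numeric ranges `[lo, hi)`. Bins must be disjoint; rows matching no bin are
#' counted under `"other"`.
#'
#' @param sheet An `index_sheet`.
#' @param column Column name.
#' @param bins List (optionally named) of scalars and/or `c(lo, hi)` ranges.
#' @return A tibble `bin`, `count`, bins in input order plus `other`.
#' @examples
#' sheet <- build_index(list())
#' classify_counts(sheet, "kVp", list(`120` = 120, `100` = 100))
#' @export
classify_counts <- function(sheet, column, bins) {
  check_columns(sheet, column)
  if (!is.list(bins)) bins <- as.list(bins)
  labels <- names(bins)
  if (is.null(labels)) labels <- rep("", length(bins))
  labels <- ifelse(labels == "",
                   vapply(bins, function(b) paste(b, collapse = "-"), character(1)),
                   labels)
  if (anyDuplicated(labels)) {
    abort("bin labels must be unique", class = "ctcurate_config_error")
  }
  values <- sheet[[column]]
  match_mat <- vapply(bins, function(b) bin_matches(values, b),
                      logical(length(values)))
  match_mat <- matrix(match_mat, nrow = length(values))
  if (length(values) && any(rowSums(match_mat) > 1)) {
    abort("bins overlap: at least one row matches two bins",
          class = "ctcurate_config_error")
  }
  counts <- colSums(match_mat)
  other <- if (length(values)) sum(rowSums(match_mat) == 0) else 0
  tibble::tibble(bin = c(labels, "other"),
                 count = as.integer(c(counts, other)))
}

#' Write or read an index sheet as CSV
#'
#' UTF-8, comma-delimited, header row, quoted text fields; blank cells stay
#' empty strings so the round trip is cell-for-cell exact.
#'
#' @param sheet An `index_sheet`.
#' @param path CSV file path.
#' @return `read_index()` returns the `index_sheet`.
#' @export
write_index <- function(sheet, path) {
  readr::write_csv(as_index_sheet(sheet), path, na = "", quote = "needed")
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  spec <- setNames(lapply(index_columns(), function(cl) readr::col_character()),
                   index_columns())
  sheet <- readr::read_csv(path, col_types = do.call(readr::cols, spec),
                           na = character(), progress = FALSE)
  for (cl in .index_numeric_cols) {
    v <- sheet[[cl]]
    v[v == ""] <- NA_character_
    sheet[[cl]] <- as.numeric(v)
  }
  as_index_sheet(sheet)
}
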