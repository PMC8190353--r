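## DICOM Part-10 codec for uncompressed Explicit VR Little Endian.
## This is deliberately minimal: single-frame CT slices, no sequences beyond
## skipping, no other transfer syntaxes (the fixture generator only emits
## Explicit VR LE, and TCIA-style CT archives decompress to it).

.ts_explicit_le <- "1.2.840.10008.1.2.1"
.sop_class_ct <- "1.2.840.10008.5.1.4.1.1.2"
.uid_root <- "1.2.826.0.1.3680043.9999"

## VRs that use the 4-byte length form (2 reserved bytes before the length).
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.text_vrs <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
               "TM", "UC", "UR", "UT", "UI")
.num_str_vrs <- c("DS", "IS")

new_element <- function(group, element, vr, value) {
  list(group = as.integer(group), element = as.integer(element),
       vr = vr, value = value)
}

#' Read one DICOM file into an image-instance object
#'
#' Parses a DICOM Part-10 file (Explicit VR Little Endian) into a
#' `dicom_instance`: a keyed collection of data elements plus the decoded
#' pixel plane. An element written with zero length is kept as
#' *present-but-empty* (length-0 value), which is distinct from an absent
#' element -- the distinction matters for type-1/2 attribute validation.
#'
#' @param path Path to a `.dcm`/`.ima` (or extension-less) Part-10 file; the
#'   `DICM` magic is sniffed, the extension is not trusted.
#' @return A `dicom_instance` with fields `elements` (named list keyed by
#'   `"GGGG,EEEE"`), `pixel` (integer matrix of stored values, rows x cols,
#'   or `NULL`), and `path`.
#' @seealso [dcm_value()], [effective_slice_location()], [read_series()]
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "ctcurate_io_error")
  }
  n <- file.info(path)$size
  if (is.na(n) || n < 132) {
    abort(sprintf("not a DICOM Part-10 file (too short): %s", path),
          class = "ctcurate_format_error")
  }
  raw <- readBin(path, "raw", n = n)
  if (rawToChar(raw[129:132]) != "DICM") {
    abort(sprintf("not a DICOM Part-10 file (no DICM magic): %s", path),
          class = "ctcurate_format_error")
  }
  pos <- 133L
  elements <- list()
  meta <- list()
  pixel <- NULL
  rows <- cols <- NA_integer_
  ts <- NULL

  read_u16 <- function(at) {
    sum(as.integer(raw[at:(at + 1L)]) * c(1L, 256L))
  }
  read_u32 <- function(at) {
    sum(as.numeric(raw[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
  }

  while (pos <= n) {
    if (pos + 7L > n) {
      abort(sprintf("truncated element header at byte %d: %s", pos, path),
            class = "ctcurate_corrupt_error")
    }
    grp <- read_u16(pos); el <- read_u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort(sprintf("unsupported encoding (implicit VR or corrupt) at byte %d: %s",
                    pos, path), class = "ctcurate_format_error")
    }
    if (vr %in% .long_vrs) {
      len <- read_u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- read_u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (len == 0xFFFFFFFF) {
      abort(sprintf("undefined-length element (%04X,%04X) unsupported: %s",
                    grp, el, path), class = "ctcurate_format_error")
    }
    if (vstart + len - 1L > n) {
      abort(sprintf("truncated value for element (%04X,%04X): %s", grp, el, path),
            class = "ctcurate_corrupt_error")
    }
    bytes <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- tag_key(grp, el)
    value <- decode_value(vr, bytes)
    if (grp == 0x0002L) {
      # file meta group: tracked separately, regenerated on write
      if (key == "0002,0010") ts <- value
      meta[[key]] <- value
      pos <- vstart + len
      next
    }
    if (key == "0028,0010" && length(value)) rows <- as.integer(value)
    if (key == "0028,0011" && length(value)) cols <- as.integer(value)
    if (key == "7FE0,0010") {
      if (!is.na(rows) && !is.na(cols)) {
        if (len != rows * cols * 2L) {
          abort(sprintf("pixel data length %d does not match %dx%d uint16: %s",
                        len, rows, cols, path), class = "ctcurate_corrupt_error")
        }
        pv <- readBin(bytes, "integer", n = rows * cols, size = 2L,
                      signed = FALSE, endian = "little")
        pixel <- matrix(pv, nrow = rows, ncol = cols, byrow = TRUE)
      }
      value <- len  # keep presence + byte length, pixels live in $pixel
    }
    elements[[key]] <- new_element(grp, el, vr, value)
    pos <- vstart + len
    if (len %% 2L == 1L) pos <- pos + 1L  # defensive; writer always pads even
  }
  if (!is.null(ts) && length(ts) && ts != .ts_explicit_le) {
    abort(sprintf("unsupported transfer syntax '%s': %s", ts, path),
          class = "ctcurate_format_error")
  }
  structure(list(path = path, meta = meta, elements = elements, pixel = pixel),
            class = "dicom_instance")
}

decode_value <- function(vr, bytes) {
  if (length(bytes) == 0) {
    return(if (vr %in% c("US", "UL", "SS", "SL", "FL", "FD")) numeric(0)
           else if (vr %in% .num_str_vrs) numeric(0)
           else character(0))
  }
  if (vr == "US") {
    return(readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                   signed = FALSE, endian = "little"))
  }
  if (vr == "UL") {
    return(readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                   endian = "little"))
  }
  if (vr == "SS") {
    return(readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                   signed = TRUE, endian = "little"))
  }
  if (vr == "FD") {
    return(readBin(bytes, "double", n = length(bytes) / 8L, endian = "little"))
  }
  if (vr == "FL") {
    return(readBin(bytes, "double", n = length(bytes) / 4L, size = 4L,
                   endian = "little"))
  }
  if (vr %in% c("OB", "OW", "OF", "UN", "SQ")) {
    return(bytes)
  }
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  txt <- sub("[ ]+$", "", txt)
  parts <- strsplit(txt, "\\", fixed = TRUE)[[1]]
  if (length(parts) == 0) parts <- ""
  parts <- trimws(parts)
  if (vr %in% .num_str_vrs) {
    num <- suppressWarnings(as.numeric(parts))
    return(num)
  }
  parts
}

encode_value <- function(vr, value) {
  if (is.null(value) || length(value) == 0) return(raw(0))
  if (vr == "US") {
    return(writeBin(as.integer(value), raw(), size = 2L, endian = "little"))
  }
  if (vr == "UL") {
    return(writeBin(as.integer(value), raw(), size = 4L, endian = "little"))
  }
  if (vr == "FD") {
    return(writeBin(as.numeric(value), raw(), endian = "little"))
  }
  if (vr %in% c("OB", "OW")) {
    return(as.raw(value))
  }
  if (vr %in% .num_str_vrs) {
    value <- vapply(value, function(x) format(x, scientific = FALSE, trim = TRUE),
                    character(1))
  }
  txt <- paste(as.character(value), collapse = "\\")
  bytes <- charToRaw(txt)
  if (length(bytes) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  bytes
}

encode_element <- function(el) {
  bytes <- encode_value(el$vr, el$value)
  hdr <- c(
    writeBin(as.integer(el$group), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(el$element), raw(), size = 2L, endian = "little"),
    charToRaw(el$vr)
  )
  if (el$vr %in% .long_vrs) {
    hdr <- c(hdr, as.raw(c(0, 0)),
             writeBin(length(bytes), raw(), size = 4L, endian = "little"))
  } else {
    hdr <- c(hdr, writeBin(length(bytes), raw(), size = 2L, endian = "little"))
  }
  c(hdr, bytes)
}

## Write a Part-10 file from a named element list (keys "GGGG,EEEE") and an
## optional integer pixel matrix of stored values. Elements are emitted in
## ascending tag order; group 0002 file meta is generated here.
write_dicom <- function(path, elements, pixel = NULL) {
  if (!is.null(pixel)) {
    pv <- as.integer(t(pixel))  # row-major on disk
    bytes <- writeBin(pv, raw(), size = 2L, endian = "little")
    elements[["7FE0,0010"]] <- new_element(0x7FE0L, 0x0010L, "OW", bytes)
  }
  sop_uid <- elements[["0008,0018"]]$value %||% paste0(.uid_root, ".0")
  meta <- list(
    new_element(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    new_element(0x0002L, 0x0002L, "UI", .sop_class_ct),
    new_element(0x0002L, 0x0003L, "UI", sop_uid[1]),
    new_element(0x0002L, 0x0010L, "UI", .ts_explicit_le),
    new_element(0x0002L, 0x0012L, "UI", paste0(.uid_root, ".1")),
    new_element(0x0002L, 0x0013L, "SH", "ctcurate")
  )
  meta_bytes <- unlist(lapply(meta, encode_element))
  group_len <- new_element(0x0002L, 0x0000L, "UL", length(meta_bytes))
  ord <- order(
    vapply(elements, function(e) e$group, integer(1)),
    vapply(elements, function(e) e$element, integer(1))
  )
  body <- unlist(lapply(elements[ord], encode_element))
  out <- c(raw(128), charToRaw("DICM"), encode_element(group_len),
           meta_bytes, body)
  writeBin(out, path)
  invisible(path)
}

#' Access a data element value by tag
#'
#' @param inst A `dicom_instance`.
#' @param tag `"GGGG,EEEE"`, a dictionary keyword, or `c(group, element)`.
#' @return The decoded value (`NULL` when the element is absent; a length-0
#'   vector when present-but-empty).
#' @export
dcm_value <- function(inst, tag) {
  el <- inst$elements[[as_tag_key(tag)]]
  if (is.null(el)) NULL else el$value
}

#' @rdname dcm_value
#' @export
dcm_present <- function(inst, tag) {
  !is.null(inst$elements[[as_tag_key(tag)]])
}

#' @rdname dcm_value
#' @export
dcm_empty <- function(inst, tag) {
  el <- inst$elements[[as_tag_key(tag)]]
  !is.null(el) && length(el$value) == 0
}

## First value as a number, NA when absent/empty/non-numeric.
dcm_num1 <- function(inst, tag) {
  v <- dcm_value(inst, tag)
  if (is.null(v) || length(v) == 0) return(NA_real_)
  suppressWarnings(as.numeric(v[1]))
}

dcm_chr1 <- function(inst, tag) {
  v <- dcm_value(inst, tag)
  if (is.null(v) || length(v) == 0) return(NA_character_)
  as.character(v[1])
}

#' Tabulate the elements of an instance
#'
#' @param inst A `dicom_instance`.
#' @return A tibble with one row per data element: `tag`, `keyword`, `vr`,
#'   `n_values`, `value` (list-column).
#' @export
dcm_elements <- function(inst) {
  keys <- names(inst$elements)
  tibble::tibble(
    tag = keys,
    keyword = keyword_for(keys),
    vr = vapply(inst$elements, function(e) e$vr, character(1), USE.NAMES = FALSE),
    n_values = vapply(inst$elements, function(e) length(e$value), integer(1),
                      USE.NAMES = FALSE),
    value = unname(lapply(inst$elements, function(e) e$value))
  )
}

#' @export
print.dicom_instance <- function(x, ...) {
  cat(sprintf("<dicom_instance> %s\n", dcm_chr1(x, "SOPInstanceUID") %||% ""))
  cat(sprintf("  %d elements; pixel plane: %s\n", length(x$elements),
              if (is.null(x$pixel)) "none"
              else paste(dim(x$pixel), collapse = " x ")))
  invisible(x)
}

#' Rescale stored pixel values to Hounsfield units
#'
#' Applies the modality rescale `HU = slope * stored + intercept` from the
#' instance's rescale tags (defaulting to slope 1, intercept 0 when absent).
#'
#' @param inst A `dicom_instance` with a pixel plane.
#' @return Numeric matrix of HU values.
#' @export
pixel_hu <- function(inst) {
  if (is.null(inst$pixel)) {
    abort("instance has no pixel data", class = "ctcurate_geometry_error")
  }
  slope <- dcm_num1(inst, "RescaleSlope")
  inter <- dcm_num1(inst, "RescaleIntercept")
  if (is.na(slope)) slope <- 1
  if (is.na(inter)) inter <- 0
  slope * inst$pixel + inter
}
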