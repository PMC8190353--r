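## Minimal DICOM data dictionary: the CT image attributes this toolkit reads,
## writes and validates. Not a full PS3.6 dictionary by design.

.dicom_dict <- local({
  d <- rbind(
    c(0x0002L, 0x0000L, "UL", "FileMetaInformationGroupLength"),
    c(0x0002L, 0x0001L, "OB", "FileMetaInformationVersion"),
    c(0x0002L, 0x0002L, "UI", "MediaStorageSOPClassUID"),
    c(0x0002L, 0x0003L, "UI", "MediaStorageSOPInstanceUID"),
    c(0x0002L, 0x0010L, "UI", "TransferSyntaxUID"),
    c(0x0002L, 0x0012L, "UI", "ImplementationClassUID"),
    c(0x0002L, 0x0013L, "SH", "ImplementationVersionName"),
    c(0x0008L, 0x0008L, "CS", "ImageType"),
    c(0x0008L, 0x0016L, "UI", "SOPClassUID"),
    c(0x0008L, 0x0018L, "UI", "SOPInstanceUID"),
    c(0x0008L, 0x0020L, "DA", "StudyDate"),
    c(0x0008L, 0x0030L, "TM", "StudyTime"),
    c(0x0008L, 0x0060L, "CS", "Modality"),
    c(0x0008L, 0x0070L, "LO", "Manufacturer"),
    c(0x0008L, 0x103EL, "LO", "SeriesDescription"),
    c(0x0010L, 0x0010L, "PN", "PatientName"),
    c(0x0010L, 0x0020L, "LO", "PatientID"),
    c(0x0010L, 0x0040L, "CS", "PatientSex"),
    c(0x0010L, 0x1010L, "AS", "PatientAge"),
    c(0x0018L, 0x0050L, "DS", "SliceThickness"),
    c(0x0018L, 0x0060L, "DS", "KVP"),
    c(0x0018L, 0x1150L, "IS", "ExposureTime"),
    c(0x0018L, 0x1151L, "IS", "XRayTubeCurrent"),
    c(0x0018L, 0x1210L, "SH", "ConvolutionKernel"),
    c(0x0018L, 0x5100L, "CS", "PatientPosition"),
    c(0x0020L, 0x000DL, "UI", "StudyInstanceUID"),
    c(0x0020L, 0x000EL, "UI", "SeriesInstanceUID"),
    c(0x0020L, 0x0010L, "SH", "StudyID"),
    c(0x0020L, 0x0011L, "IS", "SeriesNumber"),
    c(0x0020L, 0x0013L, "IS", "InstanceNumber"),
    c(0x0020L, 0x0032L, "DS", "ImagePositionPatient"),
    c(0x0020L, 0x0037L, "DS", "ImageOrientationPatient"),
    c(0x0020L, 0x1041L, "DS", "SliceLocation"),
    c(0x0028L, 0x0002L, "US", "SamplesPerPixel"),
    c(0x0028L, 0x0004L, "CS", "PhotometricInterpretation"),
    c(0x0028L, 0x0010L, "US", "Rows"),
    c(0x0028L, 0x0011L, "US", "Columns"),
    c(0x0028L, 0x0030L, "DS", "PixelSpacing"),
    c(0x0028L, 0x0100L, "US", "BitsAllocated"),
    c(0x0028L, 0x0101L, "US", "BitsStored"),
    c(0x0028L, 0x0102L, "US", "HighBit"),
    c(0x0028L, 0x0103L, "US", "PixelRepresentation"),
    c(0x0028L, 0x1050L, "DS", "WindowCenter"),
    c(0x0028L, 0x1051L, "DS", "WindowWidth"),
    c(0x0028L, 0x1052L, "DS", "RescaleIntercept"),
    c(0x0028L, 0x1053L, "DS", "RescaleSlope"),
    c(0x0012L, 0x0010L, "LO", "ClinicalTrialSponsorName"),
    c(0x0012L, 0x0020L, "LO", "ClinicalTrialProtocolID"),
    c(0x0018L, 0x0010L, "LO", "ContrastBolusAgent"),
    c(0x7FE0L, 0x0010L, "OW", "PixelData")
  )
  tibble::tibble(
    group   = as.integer(d[, 1]),
    element = as.integer(d[, 2]),
    vr      = d[, 3],
    keyword = d[, 4]
  )
})

#' Format a DICOM tag as `"GGGG,EEEE"`
#'
#' @param group,element Integer tag group and element (each in
#'   `[0x0000, 0xFFFF]`).
#' @return Character tag key, e.g. `"0020,1041"`.
#' @examples
#' tag_key(0x0020, 0x1041)
#' @export
tag_key <- function(group, element) {
  stopifnot(all(group >= 0 & group <= 0xFFFF), all(element >= 0 & element <= 0xFFFF))
  sprintf("%04X,%04X", as.integer(group), as.integer(element))
}

#' Look up a DICOM tag by keyword
#'
#' @param keyword Attribute keyword, e.g. `"SliceLocation"`.
#' @return Tag key string (`"GGGG,EEEE"`).
#' @export
tag_for <- function(keyword) {
  i <- match(keyword, .dicom_dict$keyword)
  if (is.na(i)) {
    abort(sprintf("unknown DICOM keyword '%s'", keyword), class = "ctcurate_dict_error")
  }
  tag_key(.dicom_dict$group[i], .dicom_dict$element[i])
}

## Inverse lookup; NA when the tag is not in the shipped dictionary.
keyword_for <- function(key) {
  keys <- tag_key(.dicom_dict$group, .dicom_dict$element)
  .dicom_dict$keyword[match(key, keys)]
}

vr_for <- function(key) {
  keys <- tag_key(.dicom_dict$group, .dicom_dict$element)
  .dicom_dict$vr[match(key, keys)]
}

## Accept "GGGG,EEEE", a keyword, or c(group, element); return the key string.
as_tag_key <- function(tag) {
  if (is.numeric(tag) && length(tag) == 2) {
    return(tag_key(tag[1], tag[2]))
  }
  if (is.character(tag) && length(tag) == 1) {
    if (grepl("^[0-9A-Fa-f]{4},[0-9A-Fa-f]{4}$", tag)) {
      return(toupper(tag))
    }
    return(tag_for(tag))
  }
  abort("tag must be 'GGGG,EEEE', a keyword, or c(group, element)",
        class = "ctcurate_dict_error")
}
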