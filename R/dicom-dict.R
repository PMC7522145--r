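# Data element dictionary: the subset of the standard needed by the
# synthetic PACS, the query/retrieve client and the de-identifier.
# VRs follow the standard; `basic` marks attributes a C-FIND style
# query may return (the restricted header set), everything else is
# only available from the full data set.
.dicom_dict <- local({
  d <- rbind(
    c("0008,0005", "CS", "SpecificCharacterSet",        FALSE),
    c("0008,0016", "UI", "SOPClassUID",                 FALSE),
    c("0008,0018", "UI", "SOPInstanceUID",              TRUE),
    c("0008,0020", "DA", "StudyDate",                   TRUE),
    c("0008,0030", "TM", "StudyTime",                   TRUE),
    c("0008,0050", "SH", "AccessionNumber",             TRUE),
    c("0008,0060", "CS", "Modality",                    TRUE),
    c("0008,0070", "LO", "Manufacturer",                FALSE),
    c("0008,0080", "LO", "InstitutionName",             FALSE),
    c("0008,0081", "ST", "InstitutionAddress",          FALSE),
    c("0008,0090", "PN", "ReferringPhysicianName",      FALSE),
    c("0008,1010", "SH", "StationName",                 FALSE),
    c("0008,1030", "LO", "StudyDescription",            TRUE),
    c("0008,103E", "LO", "SeriesDescription",           TRUE),
    c("0008,1070", "PN", "OperatorsName",               FALSE),
    c("0008,1090", "LO", "ManufacturerModelName",       FALSE),
    c("0010,0010", "PN", "PatientName",                 FALSE),
    c("0010,0020", "LO", "PatientID",                   TRUE),
    c("0010,0030", "DA", "PatientBirthDate",            FALSE),
    c("0010,0040", "CS", "PatientSex",                  FALSE),
    c("0010,1000", "LO", "OtherPatientIDs",             FALSE),
    c("0010,1001", "PN", "OtherPatientNames",           FALSE),
    c("0010,1040", "LO", "PatientAddress",              FALSE),
    c("0018,0015", "CS", "BodyPartExamined",            FALSE),
    c("0018,1000", "LO", "DeviceSerialNumber",          FALSE),
    c("0018,1020", "LO", "SoftwareVersions",            FALSE),
    c("0018,1030", "LO", "ProtocolName",                FALSE),
    c("0020,000D", "UI", "StudyInstanceUID",            TRUE),
    c("0020,000E", "UI", "SeriesInstanceUID",           TRUE),
    c("0020,0011", "IS", "SeriesNumber",                TRUE),
    c("0020,0013", "IS", "InstanceNumber",              TRUE),
    c("0020,1206", "IS", "NumberOfStudyRelatedSeries",  TRUE),
    c("0020,1208", "IS", "NumberOfStudyRelatedInstances", TRUE),
    c("0028,0002", "US", "SamplesPerPixel",             FALSE),
    c("0028,0004", "CS", "PhotometricInterpretation",   FALSE),
    c("0028,0010", "US", "Rows",                        FALSE),
    c("0028,0011", "US", "Columns",                     FALSE),
    c("0028,0100", "US", "BitsAllocated",               FALSE),
    c("0028,0101", "US", "BitsStored",                  FALSE),
    c("0028,0102", "US", "HighBit",                     FALSE),
    c("0028,0103", "US", "PixelRepresentation",         FALSE),
    c("0028,1050", "DS", "WindowCenter",                FALSE),
    c("0028,1051", "DS", "WindowWidth",                 FALSE),
    c("7FE0,0010", "OW", "PixelData",                   FALSE)
  )
  df <- data.frame(tag = d[, 1], vr = d[, 2], keyword = d[, 3],
                   basic = as.logical(d[, 4]), stringsAsFactors = FALSE)
  df$group <- strtoi(substr(df$tag, 1, 4), 16L)
  df$element <- strtoi(substr(df$tag, 6, 9), 16L)
  df
})

.dict_by_keyword <- function(keyword) {
  i <- match(keyword, .dicom_dict$keyword)
  if (anyNA(i)) stop("unknown DICOM keyword(s): ",
                     paste(keyword[is.na(i)], collapse = ", "))
  .dicom_dict[i, , drop = FALSE]
}

#' Attributes returned by a restricted (C-FIND style) header query
#'
#' The restricted header set a PACS exposes to find-level queries:
#' identifiers, study/series descriptions, modality, accession number,
#' instance number and study-related counts. Full headers (device,
#' protocol, institution, patient demographics, pixel geometry) require
#' retrieval of the complete data set.
#'
#' @return Character vector of DICOM attribute keywords.
#' @export
basic_header_keys <- function() {
  .dicom_dict$keyword[.dicom_dict$basic]
}

#' Map a DICOM value representation to a warehouse value type
#'
#' The entity-attribute-value store types every attribute as text,
#' number or date. The mapping from DICOM value representations is
#' shipped as a configuration file and can be overridden per site.
#'
#' @param vr Character vector of DICOM value representations (e.g. "DA").
#' @param table Optional named character vector overriding the shipped
#'   VR-to-type table.
#' @return Character vector, each element one of "text", "number", "date".
#' @export
vr_value_type <- function(vr, table = NULL) {
  if (is.null(table)) table <- .vr_type_table()
  out <- unname(table[vr])
  out[is.na(out)] <- "text"
  out
}

.vr_type_cache <- new.env(parent = emptyenv())

.vr_type_table <- function() {
  if (is.null(.vr_type_cache$tab)) {
    path <- system.file("extdata", "vr_types.json", package = "pacsdwh")
    tab <- unlist(jsonlite::read_json(path))
    .vr_type_cache$tab <- tab
  }
  .vr_type_cache$tab
}

.keyword_vr <- function(keyword) .dict_by_keyword(keyword)$vr
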