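# Header de-identification and the modality black/white-list.
# De-identification removes a configured set of directly identifying
# attributes and replaces linkage identifiers (PatientID, AccessionNumber,
# the three instance UIDs) with pseudonymous values, preserving the
# study/series/image hierarchy. Pixel payloads are untouched: burned-in
# identifying text (notably in ultrasound) is handled by blocking the
# modality for image retrieval, not by pixel redaction.

.DEFAULT_REMOVE <- c(
  "PatientName", "PatientBirthDate", "PatientAddress", "OtherPatientIDs",
  "OtherPatientNames", "ReferringPhysicianName", "OperatorsName",
  "InstitutionAddress"
)

.DEFAULT_REPLACE <- c(
  PatientID = "patient", AccessionNumber = "accession_number",
  StudyInstanceUID = "instance_uid", SeriesInstanceUID = "instance_uid",
  SOPInstanceUID = "instance_uid"
)

#' De-identification profile
#'
#' The removed attribute set is configurable because the exact ruling is
#' site-specific (data protection officer's decision); the default
#' removes direct identifiers (name, birth date, addresses, other
#' patient IDs/names, referring/operating physician, institution
#' address) and replaces the linkage identifiers with pseudonyms, in
#' line with standard DICOM de-identification practice.
#'
#' @param tags_to_remove Character vector of attribute keywords removed
#'   outright.
#' @param tags_to_replace Named character vector: attribute keyword ->
#'   pseudonym kind (`"patient"`, `"accession_number"`, `"instance_uid"`).
#' @param modality_blocklist Modality codes denied for image retrieval
#'   (default `"US"`: ultrasound images carry burned-in identifying text).
#' @param modality_allowlist Optional explicit allow list for image
#'   retrieval; must be disjoint from the blocklist.
#' @return Object of class `deid_profile`.
#' @export
deid_profile <- function(tags_to_remove = .DEFAULT_REMOVE,
                         tags_to_replace = .DEFAULT_REPLACE,
                         modality_blocklist = "US",
                         modality_allowlist = NULL) {
  p <- structure(list(tags_to_remove = tags_to_remove,
                      tags_to_replace = tags_to_replace,
                      modality_blocklist = modality_blocklist,
                      modality_allowlist = modality_allowlist),
                 class = "deid_profile")
  validate_deid_profile(p)
  p
}

validate_deid_profile <- function(p) {
  overlap <- intersect(p$tags_to_remove, names(p$tags_to_replace))
  if (length(overlap))
    stop("deid profile: attributes both removed and replaced: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  both <- intersect(p$modality_blocklist, p$modality_allowlist)
  if (length(both))
    stop("deid profile: modalities on both block and allow list: ",
         paste(both, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Read a de-identification profile from YAML
#'
#' @param path YAML file with any of the [deid_profile()] fields.
#' @return A `deid_profile`.
#' @export
read_deid_profile <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$tags_to_replace)) cfg$tags_to_replace <- unlist(cfg$tags_to_replace)
  defaults <- list(tags_to_remove = .DEFAULT_REMOVE,
                   tags_to_replace = .DEFAULT_REPLACE,
                   modality_blocklist = "US", modality_allowlist = NULL)
  do.call(deid_profile, utils::modifyList(defaults, cfg))
}

#' Anonymize one DICOM record
#'
#' Returns a copy of the record with every `tags_to_remove` attribute
#' absent and every `tags_to_replace` attribute replaced by the
#' pseudonym supplied by `pseudonymize`. All other attributes and the
#' pixel payload are unchanged; the input record is not modified. The
#' operation is atomic: an unresolvable pseudonym aborts with an error
#' naming the identifier and no partially de-identified record is
#' returned.
#'
#' @param record A `dicom_record` (list with `attrs`, identifier fields).
#' @param profile A [deid_profile()].
#' @param pseudonymize Function `(kind, value) -> pseudonym`, e.g.
#'   [connector_pseudonymizer()]. Instance-UID kinds must yield valid
#'   UIDs.
#' @return The anonymized `dicom_record`.
#' @export
anonymize <- function(record, profile, pseudonymize) {
  validate_deid_profile(profile)
  attrs <- record$attrs
  replacements <- list()
  for (kw in intersect(names(profile$tags_to_replace), names(attrs))) {
    kind <- profile$tags_to_replace[[kw]]
    value <- attrs[[kw]]
    psn <- pseudonymize(kind, value)
    if (is.null(psn) || length(psn) != 1L || is.na(psn))
      stop("cannot pseudonymize ", kw, " value '", value, "'", call. = FALSE)
    replacements[[kw]] <- psn
  }
  attrs[intersect(profile$tags_to_remove, names(attrs))] <- NULL
  for (kw in names(replacements)) attrs[[kw]] <- replacements[[kw]]
  out <- record
  out$attrs <- attrs
  for (f in c("patient_id", "study_uid", "series_uid", "sop_uid")) {
    kw <- switch(f, patient_id = "PatientID", study_uid = "StudyInstanceUID",
                 series_uid = "SeriesInstanceUID", sop_uid = "SOPInstanceUID")
    kind <- unname(profile$tags_to_replace[kw])
    if (!is.null(out[[f]]) && length(kind) == 1L && !is.na(kind))
      out[[f]] <- pseudonymize(kind, out[[f]])
  }
  out$anonymized <- TRUE
  out
}

#' Decide whether an operation on a modality is allowed
#'
#' Image retrieval is denied for block-listed modalities (and, when an
#' allow list is configured, for modalities outside it). Metadata
#' operations are always allowed regardless of modality: the restriction
#' exists because of identifying pixel content, which metadata queries
#' never touch. The decision is total: every (modality, operation) pair
#' yields exactly one allow/deny with a machine-readable reason.
#'
#' @param profile A [deid_profile()].
#' @param modality Modality code (non-empty string).
#' @param operation `"metadata"` or `"image"`.
#' @return List with `allow` (logical) and `reason` (string).
#' @export
check_modality_policy <- function(profile, modality,
                                  operation = c("metadata", "image")) {
  operation <- match.arg(operation)
  stopifnot(is.character(modality), nzchar(modality))
  if (operation == "metadata")
    return(list(allow = TRUE, reason = "metadata_always_allowed"))
  if (modality %in% profile$modality_blocklist)
    return(list(allow = FALSE, reason = "modality_blocklisted"))
  if (!is.null(profile$modality_allowlist) &&
      !modality %in% profile$modality_allowlist)
    return(list(allow = FALSE, reason = "modality_not_on_allowlist"))
  list(allow = TRUE, reason = "allowed")
}
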