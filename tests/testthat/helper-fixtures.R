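# Shared fixture: one small synthetic PACS tree generated once per test
# run, plus builders for connectors and stores. All expectations in the
# tests are derived from the tree's index (brute force), never from the
# code paths under test.

.fixtures <- new.env(parent = emptyenv())

fixture_spec <- function() {
  cohort_spec(
    n_patients = 12L, seed = 101L, p_has_imaging = 0.85,
    studies_dist = list(meanlog = log(2), sdlog = 0.6),
    series_per_study_dist = list(meanlog = log(2), sdlog = 0.5),
    images_per_series_dist = list(meanlog = log(3), sdlog = 0.5,
                                  patient_sdlog = 0.3),
    size_scale = 1 / 32,
    inconsistency_rate = 0.08, report_fraction = 0.8)
}

fixture_tree <- function() {
  if (is.null(.fixtures$tree)) {
    root <- file.path(tempdir(), "pacsdwh-fixture-tree")
    unlink(root, recursive = TRUE)
    .fixtures$tree <- gen_cohort(fixture_spec(), root)
  }
  .fixtures$tree
}

fixture_provider <- function() {
  if (is.null(.fixtures$provider)) .fixtures$provider <- qr_provider(fixture_tree())
  .fixtures$provider
}

fixture_connector <- function() {
  if (is.null(.fixtures$connector))
    .fixtures$connector <- hmac_connector("fixture-secret")
  .fixtures$connector
}

fixture_pseudonyms <- function() {
  conn <- fixture_connector()
  conn$pseudonymize("patient", fixture_tree()$cohort$patients$patient_id)
}

new_store <- function() eav_store(tempfile(fileext = ".sqlite"))

# a stand-alone record resembling a retrieved data set, for deid tests
make_record <- function(patient_id = "PID000042",
                        study_uid = "1.2.840.1.1", series_uid = "1.2.840.1.1.1",
                        sop_uid = "1.2.840.1.1.1.1") {
  structure(list(
    patient_id = patient_id, study_uid = study_uid, series_uid = series_uid,
    sop_uid = sop_uid,
    attrs = list(PatientID = patient_id, PatientName = "DOE^JANE",
                 PatientBirthDate = "19501231", PatientSex = "F",
                 PatientAddress = "1 Real Street",
                 OtherPatientIDs = "HIS-42",
                 ReferringPhysicianName = "REF^DOC",
                 OperatorsName = "OP^TECH",
                 InstitutionAddress = "Somewhere 5",
                 StudyInstanceUID = study_uid, SeriesInstanceUID = series_uid,
                 SOPInstanceUID = sop_uid, AccessionNumber = "A00000001",
                 StudyDate = "20170504", Modality = "CT",
                 StudyDescription = "CT THORAX", InstanceNumber = 1L,
                 Manufacturer = "Siemens"),
    pixel = as.raw(0:63), payload_bytes = 64),
    class = "dicom_record")
}

empty_deid_profile <- function() {
  deid_profile(tags_to_remove = character(),
               tags_to_replace = stats::setNames(character(), character()),
               modality_blocklist = character())
}
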