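# Bulk metadata extraction: find -> select -> (retrieve) -> anonymize ->
# pseudonymize -> import, for the three evaluated strategies, with
# per-patient accounting of images, elapsed seconds and transferred
# bytes. Single-threaded by design: the production PACS must never see
# parallel bulk pressure.

#' An extraction strategy
#'
#' The three evaluated combinations of header scope and image
#' selection: `basic-first` (restricted headers, first image of each
#' series), `basic-all` (restricted headers, every image) and
#' `extended-first` (full headers, first image of each series, requires
#' retrieval of the complete data sets). Other combinations are
#' rejected unless `allow_any` is set.
#'
#' @param name `"basic-first"`, `"basic-all"` or `"extended-first"`; or
#'   `NULL` when `scope`/`selection` are given directly.
#' @param scope `"basic"` or `"extended"`.
#' @param selection `"first"` or `"all"`.
#' @param allow_any Permit combinations outside the three evaluated ones.
#' @return Object of class `extraction_strategy`.
#' @export
extraction_strategy <- function(name = NULL, scope = NULL, selection = NULL,
                                allow_any = FALSE) {
  if (!is.null(name)) {
    parts <- strsplit(name, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("unknown strategy: ", name, call. = FALSE)
    scope <- parts[1]
    selection <- parts[2]
  }
  scope <- match.arg(scope, c("basic", "extended"))
  selection <- match.arg(selection, c("first", "all", "middle"))
  combo <- paste0(scope, "-", selection)
  if (!allow_any && !combo %in% c("basic-first", "basic-all", "extended-first"))
    stop("strategy ", combo, " is not one of the evaluated combinations ",
         "(basic-first, basic-all, extended-first); set allow_any to override",
         call. = FALSE)
  structure(list(scope = scope, selection = selection, name = combo),
            class = "extraction_strategy")
}

#' Serialized size of a find response
#'
#' Byte size of the key=value serialization of restricted-header
#' records, as transferred per C-FIND style response. Used by the
#' per-patient transfer accounting.
#'
#' @param headers data.frame/data.table of header records.
#' @return Total bytes (numeric scalar).
#' @export
response_bytes <- function(headers) {
  if (is.null(headers) || nrow(headers) == 0L) return(0)
  per_row <- 0
  for (col in names(headers)) {
    v <- as.character(headers[[col]])
    v[is.na(v)] <- ""
    per_row <- per_row + nchar(col, type = "bytes") +
      nchar(v, type = "bytes") + 3L   # '=', CR, LF
  }
  sum(per_row) + 16 * nrow(headers)   # fixed per-response framing
}

#' Transfer accounting over find responses and retrieved data sets
#'
#' Bytes are the serialized find-response sizes plus the file sizes of
#' retrieved data sets; records without a known payload size count zero
#' with a warning.
#'
#' @param find_responses List of header tables (see [response_bytes()]).
#' @param records List of retrieved `dicom_record`s.
#' @return List with `find_bytes`, `retrieve_bytes`, `total`.
#' @export
measure_transfer <- function(find_responses = list(), records = list()) {
  fb <- sum(vapply(find_responses, response_bytes, numeric(1)))
  pb <- vapply(records, function(r) {
    b <- r$payload_bytes
    if (is.null(b) || is.na(b)) {
      warning("record without payload size counted as zero")
      0
    } else as.numeric(b)
  }, numeric(1))
  rb <- sum(pb)
  list(find_bytes = fb, retrieve_bytes = rb, total = fb + rb)
}

#' Accession numbers of studies with a radiology report
#'
#' @param tree A `pacs_tree`.
#' @return Character vector of raw accession numbers.
#' @export
tree_report_accessions <- function(tree) {
  st <- tree$cohort$studies
  st$accession_number[st$has_report]
}

.select_per_series <- function(images, selection) {
  if (selection == "all") {
    out <- images[order(images$SeriesInstanceUID, images$InstanceNumber,
                        images$SOPInstanceUID), ]
    return(out)
  }
  rbindlist(lapply(split(images, by = "SeriesInstanceUID"),
                   select_images, method = selection))
}

.basic_import_record <- function(row, connector, pseudonym, report_acc) {
  pseudo_uid <- function(u) connector$pseudonymize("instance_uid", u)
  acc_psn <- connector$pseudonymize("accession_number", row$AccessionNumber)
  attrs <- list(
    PatientID = pseudonym,
    StudyInstanceUID = pseudo_uid(row$StudyInstanceUID),
    SeriesInstanceUID = pseudo_uid(row$SeriesInstanceUID),
    SOPInstanceUID = pseudo_uid(row$SOPInstanceUID),
    StudyDate = row$StudyDate, StudyTime = row$StudyTime,
    StudyDescription = row$StudyDescription,
    SeriesDescription = row$SeriesDescription,
    Modality = row$Modality, AccessionNumber = acc_psn,
    InstanceNumber = row$InstanceNumber)
  list(patient_pseudonym = pseudonym,
       study_uid = attrs$StudyInstanceUID,
       series_uid = attrs$SeriesInstanceUID,
       sop_uid = attrs$SOPInstanceUID,
       accession_pseudonym = acc_psn,
       has_report = row$AccessionNumber %in% report_acc,
       attrs = attrs)
}

.extended_import_record <- function(rec, connector, profile,
                                    pseudonym, report_acc) {
  # rec carries the hierarchy it was requested under (PACS index truth);
  # rec$attrs carries the file header, which externally imported files
  # may contradict -- the import quarantines those.
  raw_acc <- rec$attrs$AccessionNumber
  anon <- anonymize(rec, profile, connector_pseudonymizer(connector))
  pseudo_uid <- function(u) connector$pseudonymize("instance_uid", u)
  list(patient_pseudonym = pseudonym,
       study_uid = pseudo_uid(rec$study_uid),
       series_uid = pseudo_uid(rec$series_uid),
       sop_uid = pseudo_uid(rec$sop_uid),
       header_study_uid = anon$attrs$StudyInstanceUID,
       header_series_uid = anon$attrs$SeriesInstanceUID,
       header_sop_uid = anon$attrs$SOPInstanceUID,
       accession_pseudonym = anon$attrs$AccessionNumber,
       has_report = !is.null(raw_acc) && raw_acc %in% report_acc,
       attrs = anon$attrs)
}

#' Run a bulk extraction over a patient cohort
#'
#' For each patient pseudonym: resolves the PACS identifier through a
#' transient identity map, finds the patient's studies and images
#' (optionally within a StudyDate time frame), applies the strategy's
#' image selection, for extended scope retrieves and anonymizes the
#' full data sets, imports the pseudonymized metadata into the
#' warehouse, and releases the identity map. Patients without DICOM
#' data are flagged not-detected and contribute nothing to per-patient
#' distributions. Provider errors for one patient are recorded and do
#' not abort the run.
#'
#' @param provider A `qr_provider`.
#' @param store An [eav_store()].
#' @param connector An `id_connector`.
#' @param pseudonyms Character vector of patient pseudonyms (iterated
#'   in input order).
#' @param strategy An [extraction_strategy()] or its name.
#' @param time_from,time_to Optional StudyDate bounds (half-open).
#' @param profile [deid_profile()] applied to retrieved data sets.
#' @param report_acc Raw accession numbers that have a radiology report
#'   (e.g. [tree_report_accessions()]); used for document linkage.
#' @param clock Clock for per-patient timing (see [real_clock()]).
#' @return An `extraction_report`: `strategy`, `per_patient` table
#'   (`pseudonym`, `detected`, `n_studies`, `n_series`, `n_images`,
#'   `seconds`, `bytes`), `import` counts and cohort `totals`.
#' @export
extract_cohort <- function(provider, store, connector, pseudonyms, strategy,
                           time_from = NULL, time_to = NULL,
                           profile = deid_profile(),
                           report_acc = character(), clock = real_clock()) {
  if (is.character(strategy)) strategy <- extraction_strategy(strategy)
  stopifnot(inherits(strategy, "extraction_strategy"))
  imp_totals <- list(records = 0L, inserted = 0L, updated = 0L, linked = 0L,
                     unlinked = 0L, quarantined = 0L)
  rows <- vector("list", length(pseudonyms))
  errors <- list()
  for (pi in seq_along(pseudonyms)) {
    p <- pseudonyms[pi]
    t0 <- clock$now()
    bytes <- 0
    n_imp <- 0L
    n_studies <- 0L
    n_series <- 0L
    detected <- FALSE
    tm <- to_pacs_ids(connector, id_scope("patient", p))
    res <- try({
      if (map_size(tm) == 1L) {
        pid <- map_pacs_id(tm, p)
        studies <- qr_find(provider, qr_query("study", patient_ids = pid,
                                              time_from = time_from,
                                              time_to = time_to))
        bytes <- bytes + response_bytes(studies)
        if (nrow(studies) > 0L) {
          detected <- TRUE
          n_studies <- nrow(studies)
          images <- qr_find(provider, qr_query("image", patient_ids = pid,
                                               time_from = time_from,
                                               time_to = time_to))
          bytes <- bytes + response_bytes(images)
          n_series <- length(unique(images$SeriesInstanceUID))
          sel <- .select_per_series(images, strategy$selection)
          if (strategy$scope == "basic") {
            recs <- lapply(seq_len(nrow(sel)), function(i)
              .basic_import_record(sel[i, ], connector, p, report_acc))
          } else {
            got <- qr_retrieve(provider, sel$SOPInstanceUID, clock = clock)
            bytes <- bytes + measure_transfer(records = got)$retrieve_bytes
            recs <- lapply(got, .extended_import_record, connector = connector,
                           profile = profile, pseudonym = p,
                           report_acc = report_acc)
          }
          summ <- import_metadata(store, recs, scope = strategy$scope)
          for (f in names(imp_totals))
            imp_totals[[f]] <- imp_totals[[f]] + summ[[f]]
          n_imp <- length(recs)
        }
      }
    }, silent = TRUE)
    release_map(tm)
    if (inherits(res, "try-error")) {
      errors[[p]] <- conditionMessage(attr(res, "condition"))
      detected <- FALSE
    }
    rows[[pi]] <- data.table(pseudonym = p, detected = detected,
                             n_studies = n_studies, n_series = n_series,
                             n_images = n_imp,
                             seconds = clock$now() - t0, bytes = bytes)
  }
  per_patient <- rbindlist(rows)
  det <- per_patient[per_patient$detected, ]
  structure(list(
    strategy = strategy$name,
    per_patient = per_patient,
    import = imp_totals,
    errors = errors,
    totals = list(patients = length(pseudonyms),
                  patients_detected = sum(per_patient$detected),
                  images = sum(det$n_images),
                  series = sum(det$n_series),
                  studies = sum(det$n_studies),
                  seconds = sum(per_patient$seconds),
                  bytes = sum(per_patient$bytes))),
    class = "extraction_report")
}

#' @export
print.extraction_report <- function(x, ...) {
  cat("<extraction_report>", x$strategy, "-",
      x$totals$patients_detected, "of", x$totals$patients,
      "patients detected,", x$totals$images, "images,",
      round(x$totals$bytes / 1024, 1), "KiB\n")
  invisible(x)
}
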