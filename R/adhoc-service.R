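# Session-scoped on-demand query surface used from the data warehouse:
# study/series listing, tabular metadata queries (CSV/JSON) and image
# export (anonymized DICOM or window-leveled JPEG), with append-only
# audit of every call. Sessions are created per DWH query and can only
# touch the patients they were created for. The HTTP transport of a
# deployment is a thin adapter over these functions and is deliberately
# not part of the package.

#' Create an ad hoc query service
#'
#' @param provider A `qr_provider`.
#' @param store An [eav_store()] (used to relate exports to warehouse
#'   groups).
#' @param connector An `id_connector`.
#' @param profile [deid_profile()] governing anonymization and the
#'   modality block-list for image retrieval.
#' @param report_acc Raw accession numbers with radiology reports.
#' @param session_ttl Session lifetime in seconds (default 8 hours).
#' @param clock Clock for session expiry and audit timestamps.
#' @param audit_path Optional JSON-lines file the audit stream is
#'   appended to.
#' @return Object of class `adhoc_service`.
#' @export
adhoc_service <- function(provider, store, connector,
                          profile = deid_profile(),
                          report_acc = character(),
                          session_ttl = 8 * 3600,
                          clock = real_clock(), audit_path = NULL) {
  svc <- new.env(parent = emptyenv())
  svc$provider <- provider
  svc$store <- store
  svc$connector <- connector
  svc$profile <- profile
  svc$report_acc <- report_acc
  svc$session_ttl <- session_ttl
  svc$clock <- clock
  svc$audit_path <- audit_path
  svc$sessions <- new.env(parent = emptyenv())
  svc$audit <- list()
  class(svc) <- "adhoc_service"
  svc
}

.audit_append <- function(svc, username, operation, params, decision) {
  entry <- list(timestamp = svc$clock$now(), username = username,
                operation = operation, params = params, decision = decision)
  svc$audit[[length(svc$audit) + 1L]] <- entry
  if (!is.null(svc$audit_path))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = svc$audit_path, append = TRUE, sep = "")
  invisible(entry)
}

#' The audit stream of a service
#'
#' Append-only: one entry per service call (allow or deny) with
#' timestamp, username, operation and pseudonymous parameters only.
#'
#' @param svc An `adhoc_service`.
#' @return data.table of audit entries.
#' @export
audit_log <- function(svc) {
  rbindlist(lapply(svc$audit, function(e)
    data.table(timestamp = e$timestamp, username = e$username,
               operation = e$operation, params = e$params,
               decision = e$decision)))
}

#' Open a session scoped to a set of patients
#'
#' A DWH query involving the PACS creates a session with an unguessable
#' temporary key; the key authorizes queries for exactly the patient
#' pseudonyms in the session, until expiry.
#'
#' @param svc An `adhoc_service`.
#' @param username Authenticated DWH user.
#' @param patient_pseudonyms Non-empty character vector.
#' @return Object of class `p2d_session` (with `key`).
#' @export
create_session <- function(svc, username, patient_pseudonyms) {
  if (!is.character(username) || !nzchar(username))
    stop("username required", call. = FALSE)
  if (length(patient_pseudonyms) == 0L) {
    .audit_append(svc, username, "create_session", "patients=0", "deny")
    stop("session requires a non-empty patient set", call. = FALSE)
  }
  key <- paste0("SES-", substr(digest::digest(list(stats::runif(4),
    svc$clock$now(), username)), 1, 24))
  s <- list(key = key, username = username,
            patients = unique(patient_pseudonyms),
            created = svc$clock$now(), ttl = svc$session_ttl)
  assign(key, s, envir = svc$sessions)
  .audit_append(svc, username, "create_session",
                paste0("patients=", length(s$patients)), "allow")
  structure(s, class = "p2d_session")
}

.session_check <- function(svc, key, pseudonyms) {
  if (!exists(key, envir = svc$sessions, inherits = FALSE))
    return(list(ok = FALSE, reason = "unknown_session", session = NULL))
  s <- get(key, envir = svc$sessions)
  if (svc$clock$now() - s$created > s$ttl)
    return(list(ok = FALSE, reason = "session_expired", session = s))
  outside <- setdiff(pseudonyms, s$patients)
  if (length(outside))
    return(list(ok = FALSE, reason = "patient_not_in_session", session = s))
  list(ok = TRUE, reason = "ok", session = s)
}

.deny <- function(svc, chk, op, params) {
  user <- if (is.null(chk$session)) "<unknown>" else chk$session$username
  .audit_append(svc, user, op, params, "deny")
  stop("denied: ", chk$reason, call. = FALSE)
}

#' Check whether a session may query a patient
#'
#' @param svc An `adhoc_service`.
#' @param key Session key.
#' @param patient_pseudonym Patient to authorize.
#' @return List with `allow` and `reason`; the check itself is audited.
#' @export
authorize <- function(svc, key, patient_pseudonym) {
  chk <- .session_check(svc, key, patient_pseudonym)
  user <- if (is.null(chk$session)) "<unknown>" else chk$session$username
  .audit_append(svc, user, "authorize", paste0("patient=", patient_pseudonym),
                if (chk$ok) "allow" else "deny")
  list(allow = chk$ok, reason = chk$reason)
}

#' List a patient's DICOM studies and series
#'
#' Hierarchical listing (studies ordered by StudyDate, series by series
#' number) with descriptions and image counts, identifiers
#' pseudonymized. An empty listing for a patient without imaging is not
#' an error.
#'
#' @param svc An `adhoc_service`.
#' @param key Session key.
#' @param patient_pseudonym Patient in the session.
#' @return List of study nodes, each with a `series` list.
#' @export
list_patient_imaging <- function(svc, key, patient_pseudonym) {
  chk <- .session_check(svc, key, patient_pseudonym)
  if (!chk$ok) .deny(svc, chk, "list_patient_imaging",
                     paste0("patient=", patient_pseudonym))
  .audit_append(svc, chk$session$username, "list_patient_imaging",
                paste0("patient=", patient_pseudonym), "allow")
  tm <- to_pacs_ids(svc$connector, id_scope("patient", patient_pseudonym))
  on.exit(release_map(tm))
  if (map_size(tm) == 0L) return(list())
  pid <- map_pacs_id(tm, patient_pseudonym)
  img <- qr_find(svc$provider, qr_query("image", patient_ids = pid))
  if (nrow(img) == 0L) return(list())
  puid <- function(u) svc$connector$pseudonymize("instance_uid", u)
  studies <- split(img, img$StudyInstanceUID)
  out <- lapply(studies, function(d) {
    series <- split(d, d$SeriesInstanceUID)
    series_nodes <- lapply(series, function(s) list(
      series_uid = puid(s$SeriesInstanceUID[1]),
      description = s$SeriesDescription[1],
      modality = s$Modality[1], n_images = nrow(s)))
    names(series_nodes) <- NULL
    list(study_uid = puid(d$StudyInstanceUID[1]),
         study_date = d$StudyDate[1],
         description = d$StudyDescription[1],
         n_series = length(series_nodes),
         series = series_nodes)
  })
  names(out) <- NULL
  out[order(vapply(out, `[[`, character(1), "study_date"))]
}

#' Build an ad hoc request
#'
#' @param identifiers [id_scope()] or list of them; values are
#'   pseudonyms (patient pseudonyms, pseudonymous instance UIDs or
#'   accession pseudonyms).
#' @param time_from,time_to Optional StudyDate bounds (half-open).
#' @param format Image output format, `"dicom"` or `"jpeg"`.
#' @param modality Optional modality filter for the query.
#' @param selection Image selection per series: all/first/middle.
#' @param scope Metadata scope, `"basic"` or `"extended"`.
#' @param aggregation Result granularity: image, series or study.
#' @param type `"adhoc"` or `"bulk"`.
#' @return Object of class `adhoc_request`.
#' @export
adhoc_request <- function(identifiers, time_from = NULL, time_to = NULL,
                          format = c("dicom", "jpeg"), modality = NULL,
                          selection = c("all", "first", "middle"),
                          scope = c("basic", "extended"),
                          aggregation = c("image", "series", "study"),
                          type = c("adhoc", "bulk")) {
  if (inherits(identifiers, "id_scope")) identifiers <- list(identifiers)
  stopifnot(length(identifiers) > 0L,
            all(vapply(identifiers, inherits, logical(1), "id_scope")))
  structure(list(identifiers = identifiers, time_from = time_from,
                 time_to = time_to, format = match.arg(format),
                 modality = modality, selection = match.arg(selection),
                 scope = match.arg(scope),
                 aggregation = match.arg(aggregation),
                 type = match.arg(type)),
            class = "adhoc_request")
}

# Resolve a request to image-level find rows; enforces that every owning
# patient is inside the session. Returns rows plus the patient pseudonym
# per row.
.resolve_request <- function(svc, chk, request) {
  kinds <- vapply(request$identifiers, `[[`, character(1), "kind")
  vals <- vapply(request$identifiers, `[[`, character(1), "value")
  raw_of <- function(kind) {
    keep <- kinds == kind
    if (!any(keep)) return(NULL)
    r <- svc$connector$resolve(kind, vals[keep])
    r[!is.na(r)]
  }
  filters <- list(patient_ids = raw_of("patient"),
                  instance_uids = raw_of("instance_uid"),
                  accession_numbers = raw_of("accession_number"))
  filters <- Filter(Negate(is.null), filters)
  if (length(filters) == 0L) return(NULL)
  parts <- lapply(names(filters), function(f) {
    args <- c(list(level = "image", time_from = request$time_from,
                   time_to = request$time_to,
                   modalities = request$modality), setNames(list(filters[[f]]), f))
    qr_find(svc$provider, do.call(qr_query, args))
  })
  rows <- unique(rbindlist(parts))
  if (nrow(rows) == 0L) return(rows)
  owners <- svc$connector$pseudonymize("patient", rows$PatientID)
  outside <- setdiff(unique(owners), chk$session$patients)
  if (length(outside))
    stop("patient_not_in_session", call. = FALSE)
  rows$patient_pseudonym <- owners
  rows
}

.aggregate_rows <- function(rows, request) {
  if (request$aggregation == "image") {
    rows$n_images <- 1L
    return(rows)
  }
  by_col <- if (request$aggregation == "series") "SeriesInstanceUID"
            else "StudyInstanceUID"
  parts <- split(rows, rows[[by_col]])
  rbindlist(lapply(parts, function(d) {
    rep_ <- select_images(d, method = if (request$selection == "all") "first"
                          else request$selection)
    rep_$n_images <- nrow(d)
    if (by_col == "StudyInstanceUID")
      rep_$n_series <- length(unique(d$SeriesInstanceUID))
    rep_
  }))
}

#' Tabular metadata query
#'
#' One row per aggregation unit (image, series or study; series and
#' study rows take their attributes from the representative image under
#' the request's selection method, plus roll-up counts). Basic scope
#' answers from find responses alone; extended scope retrieves the
#' selected data sets and includes their full anonymized headers. The
#' modality block-list does not apply: this is a metadata operation.
#' Identifiers in the result are pseudonymous.
#'
#' @param svc An `adhoc_service`.
#' @param key Session key.
#' @param request An [adhoc_request()].
#' @return data.table; write with [write_adhoc_result()].
#' @export
adhoc_metadata <- function(svc, key, request) {
  pat_ids <- vapply(Filter(function(i) i$kind == "patient",
                           request$identifiers), `[[`, character(1), "value")
  chk <- .session_check(svc, key, pat_ids)
  if (!chk$ok) .deny(svc, chk, "adhoc_metadata",
                     paste0("ids=", length(request$identifiers)))
  rows <- tryCatch(.resolve_request(svc, chk, request), error = function(e) e)
  if (inherits(rows, "error")) {
    .deny(svc, list(ok = FALSE, reason = conditionMessage(rows),
                    session = chk$session),
          "adhoc_metadata", paste0("ids=", length(request$identifiers)))
  }
  .audit_append(svc, chk$session$username, "adhoc_metadata",
                paste0("ids=", length(request$identifiers),
                       " scope=", request$scope,
                       " agg=", request$aggregation), "allow")
  if (is.null(rows) || nrow(rows) == 0L) return(data.table())
  agg <- .aggregate_rows(rows, request)
  puid <- function(u) svc$connector$pseudonymize("instance_uid", u)
  pacc <- function(a) svc$connector$pseudonymize("accession_number", a)
  out <- as.data.table(agg)
  if (request$scope == "extended") {
    got <- qr_retrieve(svc$provider, out$SOPInstanceUID, clock = svc$clock)
    anon <- lapply(got, anonymize, profile = svc$profile,
                   pseudonymize = connector_pseudonymizer(svc$connector))
    ext <- rbindlist(lapply(anon, function(r) {
      a <- r$attrs[!names(r$attrs) %in% c("PixelData")]
      a <- a[!vapply(a, is.raw, logical(1))]
      dt <- as.data.table(lapply(a, function(v) paste(v, collapse = "\\")))
      dt$SOPInstanceUID_key <- r$sop_uid
      dt
    }), fill = TRUE)
    out$SOPInstanceUID_key <- vapply(out$SOPInstanceUID, puid, character(1),
                                     USE.NAMES = FALSE)
    keep <- setdiff(names(out), intersect(names(out), names(ext)))
    out <- merge(out[, c(keep, "SOPInstanceUID_key"), with = FALSE], ext,
                 by = "SOPInstanceUID_key")
    out$SOPInstanceUID_key <- NULL
    out$PatientID <- out$patient_pseudonym
  } else {
    out$PatientID <- out$patient_pseudonym
    out$StudyInstanceUID <- vapply(out$StudyInstanceUID, puid, character(1))
    out$SeriesInstanceUID <- vapply(out$SeriesInstanceUID, puid, character(1))
    out$SOPInstanceUID <- vapply(out$SOPInstanceUID, puid, character(1))
    out$AccessionNumber <- vapply(out$AccessionNumber, pacc, character(1))
  }
  out$patient_pseudonym <- NULL
  setorderv(out, intersect(c("PatientID", "StudyInstanceUID",
                             "SeriesInstanceUID", "InstanceNumber"),
                           names(out)))
  out[]
}

#' Write a metadata result as CSV or JSON
#'
#' Both renderings carry identical content (same rows, same fields).
#'
#' @param result data.table from [adhoc_metadata()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_adhoc_result <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(result, path, row.names = FALSE, na = "")
  } else {
    writeLines(jsonlite::toJSON(result, dataframe = "rows", auto_unbox = FALSE,
                                na = "null", digits = NA), path)
  }
  invisible(path)
}

.window_level <- function(v, center, width) {
  if (is.null(center) || is.null(width) || is.na(center) || is.na(width) ||
      width <= 0) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    return((v - rng[1]) / diff(rng))
  }
  pmin(1, pmax(0, (v - (center - width / 2)) / width))
}

#' Export images of an ad hoc request
#'
#' Writes the selected images of every allowed series to `out_dir`,
#' either as anonymized DICOM Part 10 files or as JPEG renderings
#' (window level from the header's WindowCenter/WindowWidth when
#' present, else min/max scaling). Series whose modality is blocked for
#' image retrieval are skipped with a per-series deny record in the
#' manifest (and in the audit entry); a wholly denied request returns
#' an explicit empty export rather than silence. The manifest links
#' every exported file to its warehouse group id.
#'
#' @param svc An `adhoc_service`.
#' @param key Session key.
#' @param request An [adhoc_request()] (uses `format` and `selection`).
#' @param out_dir Export directory (created).
#' @return List with `manifest` (data.table), `dir` and `empty_export`.
#' @export
export_images <- function(svc, key, request, out_dir) {
  pat_ids <- vapply(Filter(function(i) i$kind == "patient",
                           request$identifiers), `[[`, character(1), "value")
  chk <- .session_check(svc, key, pat_ids)
  if (!chk$ok) .deny(svc, chk, "export_images",
                     paste0("ids=", length(request$identifiers)))
  rows <- tryCatch(.resolve_request(svc, chk, request), error = function(e) e)
  if (inherits(rows, "error")) {
    .deny(svc, list(ok = FALSE, reason = conditionMessage(rows),
                    session = chk$session),
          "export_images", paste0("ids=", length(request$identifiers)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  puid <- function(u) svc$connector$pseudonymize("instance_uid", u)
  manifest <- list()
  denied_series <- character()
  if (!is.null(rows) && nrow(rows) > 0L) {
    for (d in split(rows, rows$SeriesInstanceUID)) {
      decision <- check_modality_policy(svc$profile, d$Modality[1], "image")
      series_psn <- puid(d$SeriesInstanceUID[1])
      if (!decision$allow) {
        denied_series <- c(denied_series, series_psn)
        manifest[[length(manifest) + 1L]] <- data.table(
          file = NA_character_, status = "denied", reason = decision$reason,
          patient_pseudonym = d$patient_pseudonym[1],
          study_uid = puid(d$StudyInstanceUID[1]), series_uid = series_psn,
          sop_uid = NA_character_, group_id = NA_character_)
        next
      }
      sel <- select_images(d, method = request$selection)
      got <- qr_retrieve(svc$provider, sel$SOPInstanceUID, clock = svc$clock)
      for (rec in got) {
        anon <- anonymize(rec, svc$profile,
                          connector_pseudonymizer(svc$connector))
        gid <- make_group_id(anon$study_uid, anon$series_uid, anon$sop_uid)
        ext <- if (request$format == "dicom") ".dcm" else ".jpg"
        fn <- paste0(gsub("[^0-9A-Za-z.]", "_", anon$sop_uid), ext)
        fp <- file.path(out_dir, fn)
        if (request$format == "dicom") {
          dcm_write(fp, anon$attrs, pixel = rec$pixel)
        } else {
          side_r <- anon$attrs$Rows
          side_c <- anon$attrs$Columns
          # drop the even-length padding byte a Part 10 file may carry
          v <- as.integer(rec$pixel)[seq_len(side_r * side_c)]
          m <- matrix(.window_level(v, anon$attrs$WindowCenter,
                                    anon$attrs$WindowWidth),
                      nrow = side_r, ncol = side_c, byrow = TRUE)
          jpeg::writeJPEG(m, fp)
        }
        manifest[[length(manifest) + 1L]] <- data.table(
          file = fn, status = "exported", reason = NA_character_,
          patient_pseudonym = d$patient_pseudonym[1],
          study_uid = anon$study_uid, series_uid = anon$series_uid,
          sop_uid = anon$sop_uid, group_id = gid)
      }
    }
  }
  manifest <- if (length(manifest)) rbindlist(manifest) else
    data.table(file = character(), status = character(), reason = character(),
               patient_pseudonym = character(), study_uid = character(),
               series_uid = character(), sop_uid = character(),
               group_id = character())
  empty <- !any(manifest$status == "exported")
  .audit_append(svc, chk$session$username, "export_images",
                paste0("format=", request$format,
                       " exported=", sum(manifest$status == "exported"),
                       if (length(denied_series))
                         paste0(" denied_series=",
                                paste(denied_series, collapse = ",")) else ""),
                "allow")
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  list(manifest = manifest, dir = out_dir, empty_export = empty)
}
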