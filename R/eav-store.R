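# Warehouse-side data model: an extended entity-attribute-value store
# with a document level (radiology report, keyed by accession number)
# and a group level (one group per DICOM image). Backed by a single-file
# embedded SQLite database; upserts are keyed on (group_id, attribute).
# Study/series descriptors are stored as rows of each image's group
# (duplicated per image); hierarchical roll-up is left to export.

#' Open (or create) an EAV warehouse store
#'
#' @param path SQLite database file; `":memory:"` for a transient store.
#' @return Object of class `eav_store`.
#' @export
eav_store <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS eav (
      patient_pseudonym TEXT NOT NULL,
      case_id TEXT,
      document_id TEXT NOT NULL,
      group_id TEXT NOT NULL,
      attribute TEXT NOT NULL,
      value_text TEXT, value_num REAL, value_date TEXT,
      loaded_at TEXT,
      PRIMARY KEY (group_id, attribute))")
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS groups (
      group_id TEXT PRIMARY KEY,
      document_id TEXT, patient_pseudonym TEXT,
      study_uid TEXT, series_uid TEXT, sop_uid TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS documents (
      document_id TEXT PRIMARY KEY,
      kind TEXT, accession_pseudonym TEXT, patient_pseudonym TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS catalog (
      attribute TEXT PRIMARY KEY,
      value_type TEXT, level TEXT, description TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS quarantine (
      sop_ref TEXT, study_uid TEXT, series_uid TEXT,
      reason TEXT, patient_pseudonym TEXT, at TEXT)")
  structure(list(con = con, path = path), class = "eav_store")
}

#' @rdname eav_store
#' @param store An `eav_store`.
#' @export
eav_close <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.eav_store <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) n FROM eav")$n
  g <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) n FROM groups")$n
  cat("<eav_store>", x$path, "-", n, "rows,", g, "groups\n")
  invisible(x)
}

#' Derive the EAV group identifier of one image
#'
#' One metadata group per DICOM image, identified by a fixed-width
#' cryptographic digest (truncated SHA-256) of the study, series and
#' SOP instance UIDs joined with an unambiguous separator. Plain
#' concatenation is deliberately avoided: it makes distinct UID triples
#' collide (e.g. `("A|B","C")` vs `("A","B|C")`), silently overwriting
#' existing data. Distinct triples producing the same digest would be a
#' fatal error at import.
#'
#' @param study_uid,series_uid,sop_uid Non-empty identifier strings
#'   (vectorized).
#' @return Character vector of 16-hex-digit group identifiers.
#' @export
make_group_id <- function(study_uid, series_uid, sop_uid) {
  if (any(!nzchar(study_uid)) || any(!nzchar(series_uid)) ||
      any(!nzchar(sop_uid)) || anyNA(c(study_uid, series_uid, sop_uid)))
    stop("group key components must be non-empty", call. = FALSE)
  vapply(paste(study_uid, series_uid, sop_uid, sep = "\x1f"),
         function(k) substr(digest::digest(k, algo = "sha256",
                                           serialize = FALSE), 1L, 16L),
         character(1), USE.NAMES = FALSE)
}

.split_values <- function(v) {
  if (is.character(v) && length(v) == 1L && grepl("\\\\", v))
    strsplit(v, "\\\\", fixed = FALSE)[[1]] else v
}

.attr_rows <- function(attrs) {
  # one (attribute, typed value) row per value; multi-valued attributes
  # get an index suffix from the second value on
  out <- vector("list", length(attrs))
  for (j in seq_along(attrs)) {
    kw <- names(attrs)[j]
    if (kw == "PixelData") next
    vals <- .split_values(attrs[[j]])
    if (!length(vals)) next
    known <- kw %in% .dicom_dict$keyword
    vr <- if (known) .keyword_vr(kw) else "UN"
    type <- vr_value_type(vr)
    name <- if (known) paste0("dicom.", kw)
            else paste0("dicom.tag_", gsub(",", "_", kw))
    nm <- if (length(vals) > 1L)
      c(name, paste0(name, "[", seq_along(vals)[-1L], "]")) else name
    out[[j]] <- data.table(
      attribute = nm,
      value_text = if (type == "text") as.character(vals) else NA_character_,
      value_num = if (type == "number") suppressWarnings(as.numeric(vals))
                  else NA_real_,
      value_date = if (type == "date")
        vapply(as.character(vals), function(d)
          if (grepl("^[0-9]{8}$", d))
            paste(substr(d, 1, 4), substr(d, 5, 6), substr(d, 7, 8), sep = "-")
          else d, character(1), USE.NAMES = FALSE)
        else NA_character_,
      value_type = type)
  }
  rbindlist(out[!vapply(out, is.null, logical(1))])
}

#' Import pseudonymized image metadata into the warehouse
#'
#' Creates one metadata group per image, attaches the image-level
#' attribute rows to that group, and links the group to a document:
#' the radiology report matching the (pseudonymized) accession number
#' when one exists, else a synthetic imaging document per study.
#' Re-importing the same image updates its rows instead of duplicating
#' them. Records whose file-header hierarchy identifiers disagree with
#' the identifiers they were requested under (externally imported DICOM
#' files) are quarantined with a reason and counted; the import
#' continues. A group-identifier collision between distinct UID triples
#' is fatal.
#'
#' @param store An [eav_store()].
#' @param records List of import records. Each record is a list with
#'   `patient_pseudonym`, pseudonymous `study_uid`, `series_uid`,
#'   `sop_uid`, optional `header_study_uid`/`header_series_uid`/
#'   `header_sop_uid` (as read from the file, pseudonymized), optional
#'   `accession_pseudonym`, `has_report` flag, optional `case_id`, and
#'   `attrs` (named list of already de-identified attribute values).
#' @param scope `"basic"` or `"extended"`; recorded in the catalog.
#' @return An `import_summary`: counts of records, inserted (new
#'   groups), updated, linked (to report documents), unlinked
#'   (synthetic imaging document), quarantined.
#' @export
import_metadata <- function(store, records, scope = c("basic", "extended")) {
  scope <- match.arg(scope)
  stopifnot(inherits(store, "eav_store"))
  now <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  counts <- list(records = length(records), inserted = 0L, updated = 0L,
                 linked = 0L, unlinked = 0L, quarantined = 0L)
  if (!length(records))
    return(structure(counts, class = "import_summary"))

  con <- store$con
  DBI::dbExecute(con, "BEGIN")
  on.exit(try(DBI::dbExecute(con, "ROLLBACK"), silent = TRUE), add = TRUE)
  eav_batch <- list()
  for (rec in records) {
    for (f in c("patient_pseudonym", "study_uid", "series_uid", "sop_uid"))
      if (is.null(rec[[f]]) || !nzchar(rec[[f]]))
        stop("import record missing field ", f, call. = FALSE)
    # identifier consistency: file header vs the hierarchy it was
    # requested under
    mism <- character()
    for (f in c("study_uid", "series_uid", "sop_uid")) {
      h <- rec[[paste0("header_", f)]]
      if (!is.null(h) && !identical(h, rec[[f]])) mism <- c(mism, f)
    }
    if (length(mism)) {
      DBI::dbExecute(con,
        "INSERT INTO quarantine (sop_ref, study_uid, series_uid, reason,
           patient_pseudonym, at) VALUES (:s, :st, :se, :r, :p, :a)",
        params = list(s = rec$sop_uid, st = rec$study_uid,
                      se = rec$series_uid,
                      r = paste0("identifier_mismatch:",
                                 paste(mism, collapse = "+")),
                      p = rec$patient_pseudonym, a = now))
      counts$quarantined <- counts$quarantined + 1L
      next
    }
    gid <- make_group_id(rec$study_uid, rec$series_uid, rec$sop_uid)
    prev <- DBI::dbGetQuery(con,
      "SELECT study_uid, series_uid, sop_uid FROM groups WHERE group_id = :g",
      params = list(g = gid))
    if (nrow(prev) == 1L &&
        !identical(unname(unlist(prev[1, ])),
                   c(rec$study_uid, rec$series_uid, rec$sop_uid)))
      stop("fatal: group identifier collision between distinct images",
           call. = FALSE)
    exists_already <- nrow(prev) == 1L

    has_report <- isTRUE(rec$has_report) && !is.null(rec$accession_pseudonym)
    if (has_report) {
      doc_id <- paste0("RPT-", rec$accession_pseudonym)
      kind <- "report"
      counts$linked <- counts$linked + 1L
    } else {
      doc_id <- paste0("IMG-", substr(digest::digest(rec$study_uid,
                         algo = "sha256", serialize = FALSE), 1L, 16L))
      kind <- "imaging_study"
      counts$unlinked <- counts$unlinked + 1L
    }
    DBI::dbExecute(con,
      "INSERT INTO documents (document_id, kind, accession_pseudonym,
         patient_pseudonym) VALUES (:d, :k, :acc, :p)
       ON CONFLICT(document_id) DO NOTHING",
      params = list(d = doc_id, k = kind,
                    acc = rec$accession_pseudonym %||% NA_character_,
                    p = rec$patient_pseudonym))
    DBI::dbExecute(con,
      "INSERT INTO groups (group_id, document_id, patient_pseudonym,
         study_uid, series_uid, sop_uid)
       VALUES (:g, :d, :p, :st, :se, :so)
       ON CONFLICT(group_id) DO UPDATE SET document_id = excluded.document_id",
      params = list(g = gid, d = doc_id, p = rec$patient_pseudonym,
                    st = rec$study_uid, se = rec$series_uid, so = rec$sop_uid))
    if (exists_already) counts$updated <- counts$updated + 1L
    else counts$inserted <- counts$inserted + 1L

    rows <- .attr_rows(rec$attrs)
    if (nrow(rows)) {
      rows$patient_pseudonym <- rec$patient_pseudonym
      rows$case_id <- rec$case_id %||% NA_character_
      rows$document_id <- doc_id
      rows$group_id <- gid
      rows$loaded_at <- now
      eav_batch[[length(eav_batch) + 1L]] <- rows
    }
  }
  if (length(eav_batch)) {
    all_rows <- rbindlist(eav_batch)
    # within-batch re-imports: keep the last occurrence per key
    all_rows <- all_rows[!duplicated(all_rows[, c("group_id", "attribute")],
                                     fromLast = TRUE), ]
    DBI::dbExecute(con,
      "INSERT INTO eav (patient_pseudonym, case_id, document_id, group_id,
         attribute, value_text, value_num, value_date, loaded_at)
       VALUES (:patient_pseudonym, :case_id, :document_id, :group_id,
         :attribute, :value_text, :value_num, :value_date, :loaded_at)
       ON CONFLICT(group_id, attribute) DO UPDATE SET
         value_text = excluded.value_text, value_num = excluded.value_num,
         value_date = excluded.value_date, loaded_at = excluded.loaded_at",
      params = as.list(all_rows[, c("patient_pseudonym", "case_id",
        "document_id", "group_id", "attribute", "value_text", "value_num",
        "value_date", "loaded_at")]))
    cat_rows <- unique(all_rows[, c("attribute", "value_type")])
    DBI::dbExecute(con,
      "INSERT INTO catalog (attribute, value_type, level, description)
       VALUES (:a, :t, 'image', :a) ON CONFLICT(attribute) DO NOTHING",
      params = list(a = cat_rows$attribute, t = cat_rows$value_type))
  }
  DBI::dbExecute(con, "COMMIT")
  on.exit(NULL, add = FALSE)
  structure(counts, class = "import_summary")
}

#' @export
print.import_summary <- function(x, ...) {
  cat(sprintf(
    "<import_summary> %d records: %d inserted, %d updated, %d linked, %d unlinked, %d quarantined\n",
    x$records, x$inserted, x$updated, x$linked, x$unlinked, x$quarantined))
  invisible(x)
}

# --- predicates -------------------------------------------------------------

.predicate <- function(type, attribute, ...) {
  structure(list(type = type, attribute = attribute, ...),
            class = "eav_predicate")
}

#' Warehouse query predicates
#'
#' Predicates reference cataloged attributes (namespaced, e.g.
#' `dicom.Modality`) and are combined conjunctively by [eav_query()]:
#' a patient matches when, for each predicate, at least one of their
#' groups or documents satisfies it (patient-level aggregation).
#'
#' @param attribute Cataloged attribute name.
#' @param value Comparison value.
#' @param op Numeric comparator: one of `"<", "<=", ">", ">=", "=="`.
#' @param from,to Date range bounds (inclusive from, exclusive to).
#' @param pattern Case-insensitive substring.
#' @return An `eav_predicate`.
#' @export
p_eq <- function(attribute, value) .predicate("eq", attribute, value = value)

#' @rdname p_eq
#' @export
p_cmp <- function(attribute, op, value) {
  stopifnot(op %in% c("<", "<=", ">", ">=", "=="))
  .predicate("cmp", attribute, op = op, value = as.numeric(value))
}

#' @rdname p_eq
#' @export
p_date_range <- function(attribute, from, to)
  .predicate("date_range", attribute, from = as.character(as.Date(from)),
             to = as.character(as.Date(to)))

#' @rdname p_eq
#' @export
p_contains <- function(attribute, pattern)
  .predicate("contains", attribute, pattern = pattern)

#' @rdname p_eq
#' @export
p_exists <- function(attribute) .predicate("exists", attribute)

#' @rdname p_eq
#' @export
p_not_exists <- function(attribute) .predicate("not_exists", attribute)

.attr_clause <- function() "(attribute = :a OR attribute LIKE :a || '[%')"

.predicate_patients <- function(store, pred) {
  con <- store$con
  a <- pred$attribute
  q <- switch(pred$type,
    eq = list(sql = paste0(
      "SELECT DISTINCT patient_pseudonym FROM eav WHERE ", .attr_clause(),
      " AND (value_text = :v OR value_num = :vn)"),
      params = list(a = a, v = as.character(pred$value),
                    vn = suppressWarnings(as.numeric(pred$value)))),
    cmp = list(sql = paste0(
      "SELECT DISTINCT patient_pseudonym FROM eav WHERE ", .attr_clause(),
      " AND value_num ", if (pred$op == "==") "=" else pred$op, " :v"),
      params = list(a = a, v = pred$value)),
    date_range = list(sql = paste0(
      "SELECT DISTINCT patient_pseudonym FROM eav WHERE ", .attr_clause(),
      " AND value_date >= :f AND value_date < :t"),
      params = list(a = a, f = pred$from, t = pred$to)),
    contains = list(sql = paste0(
      "SELECT DISTINCT patient_pseudonym FROM eav WHERE ", .attr_clause(),
      " AND LOWER(value_text) LIKE '%' || LOWER(:p) || '%'"),
      params = list(a = a, p = pred$pattern)),
    exists = list(sql = paste0(
      "SELECT DISTINCT patient_pseudonym FROM eav WHERE ", .attr_clause()),
      params = list(a = a)),
    not_exists = NULL)
  if (pred$type == "not_exists") {
    all_p <- DBI::dbGetQuery(con,
      "SELECT DISTINCT patient_pseudonym FROM eav")$patient_pseudonym
    with_a <- DBI::dbGetQuery(con, paste0(
      "SELECT DISTINCT patient_pseudonym FROM eav WHERE ", .attr_clause()),
      params = list(a = a))$patient_pseudonym
    return(setdiff(all_p, with_a))
  }
  params <- q$params[!vapply(q$params, function(x) length(x) == 1 && is.na(x),
                             logical(1))]
  if (!"vn" %in% names(params) && grepl(":vn", q$sql))
    q$sql <- sub("OR value_num = :vn", "", q$sql, fixed = TRUE)
  DBI::dbGetQuery(con, q$sql, params = params)$patient_pseudonym
}

#' Query the warehouse for matching patients
#'
#' Evaluates the conjunction of predicates with set semantics at
#' patient level and returns the matching patient pseudonyms. An empty
#' predicate list returns every patient with any stored row. Unknown
#' attributes raise a validation error listing the catalog.
#'
#' @param store An [eav_store()].
#' @param predicates List of [eav_predicate][p_eq]s.
#' @return Sorted character vector of patient pseudonyms, with the
#'   matching rows for those patients in attribute `"detail"`.
#' @export
eav_query <- function(store, predicates = list()) {
  stopifnot(inherits(store, "eav_store"))
  if (inherits(predicates, "eav_predicate")) predicates <- list(predicates)
  catalog <- DBI::dbGetQuery(store$con, "SELECT attribute FROM catalog")$attribute
  base_names <- unique(sub("\\[[0-9]+\\]$", "", catalog))
  for (p in predicates) {
    if (!inherits(p, "eav_predicate")) stop("not an eav_predicate", call. = FALSE)
    if (!p$attribute %in% base_names)
      stop("unknown attribute '", p$attribute, "'; catalog: ",
           paste(sort(base_names), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(predicates, function(p) .predicate_patients(store, p))
  all_p <- DBI::dbGetQuery(store$con,
    "SELECT DISTINCT patient_pseudonym FROM eav")$patient_pseudonym
  out <- if (length(sets)) sort(Reduce(intersect, sets)) else sort(all_p)
  if (length(out)) {
    qmarks <- paste(rep("?", length(out)), collapse = ",")
    detail <- DBI::dbGetQuery(store$con, paste0(
      "SELECT patient_pseudonym, document_id, group_id, attribute,
              value_text, value_num, value_date
         FROM eav WHERE patient_pseudonym IN (", qmarks, ")"),
      params = as.list(out))
  } else detail <- NULL
  structure(out, detail = detail)
}

# --- accessors & exports ----------------------------------------------------

#' Accessors for warehouse content
#'
#' @param store An [eav_store()].
#' @return data.tables of the respective store tables; `n_groups()` the
#'   number of distinct metadata groups.
#' @export
eav_rows <- function(store) as.data.table(DBI::dbGetQuery(store$con, "SELECT * FROM eav"))

#' @rdname eav_rows
#' @export
eav_groups <- function(store) as.data.table(DBI::dbGetQuery(store$con, "SELECT * FROM groups"))

#' @rdname eav_rows
#' @export
eav_documents <- function(store) as.data.table(DBI::dbGetQuery(store$con, "SELECT * FROM documents"))

#' @rdname eav_rows
#' @export
quarantine_log <- function(store) as.data.table(DBI::dbGetQuery(store$con, "SELECT * FROM quarantine"))

#' @rdname eav_rows
#' @export
n_groups <- function(store)
  DBI::dbGetQuery(store$con, "SELECT COUNT(*) n FROM groups")$n

#' Export warehouse rows as CSV
#'
#' @param store An [eav_store()].
#' @param path Output CSV path.
#' @param patients Optional pseudonym filter.
#' @return `path`, invisibly.
#' @export
eav_export_csv <- function(store, path, patients = NULL) {
  rows <- eav_rows(store)
  if (!is.null(patients)) rows <- rows[rows$patient_pseudonym %in% patients, ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Dump the attribute catalog as JSON
#'
#' @param store An [eav_store()].
#' @param path Optional output path; otherwise the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
catalog_json <- function(store, path = NULL) {
  cat_ <- DBI::dbGetQuery(store$con, "SELECT * FROM catalog ORDER BY attribute")
  js <- jsonlite::toJSON(cat_, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
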