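# Query/retrieve client: find (restricted headers) and retrieve (full
# data sets) against any provider implementing the qr_provider contract,
# plus the image selection methods used by the extraction strategies.

#' Construct a query against the PACS
#'
#' A query addresses one level of the DICOM information model and
#' combines selectors: patient identifiers, instance UIDs (study, series
#' or SOP scoped), accession numbers, modality codes and a StudyDate
#' time range. At least one selector must be present unless `allow_all`
#' is set explicitly.
#'
#' @param level One of `"patient"`, `"study"`, `"series"`, `"image"`.
#' @param patient_ids,instance_uids,accession_numbers,modalities
#'   Character vectors of selectors (`NULL` = no constraint).
#' @param time_from,time_to Optional `Date`s (or `"YYYYMMDD"`/ISO
#'   strings). The filter applies to StudyDate as the half-open interval
#'   `[time_from, time_to)`; dates carry no time of day.
#' @param allow_all Set `TRUE` to permit a query with no selectors.
#' @return Object of class `qr_query`.
#' @export
qr_query <- function(level = c("patient", "study", "series", "image"),
                     patient_ids = NULL, instance_uids = NULL,
                     accession_numbers = NULL, modalities = NULL,
                     time_from = NULL, time_to = NULL, allow_all = FALSE) {
  level <- match.arg(level)
  norm_date <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "Date")) return(format(x, "%Y%m%d"))
    x <- gsub("-", "", as.character(x))
    if (!grepl("^[0-9]{8}$", x)) stop("malformed date: ", x, call. = FALSE)
    x
  }
  q <- structure(list(level = level, patient_ids = patient_ids,
                      instance_uids = instance_uids,
                      accession_numbers = accession_numbers,
                      modalities = modalities,
                      time_from = norm_date(time_from),
                      time_to = norm_date(time_to),
                      allow_all = isTRUE(allow_all)),
                 class = "qr_query")
  validate_qr_query(q)
  q
}

#' @export
print.qr_query <- function(x, ...) {
  sel <- Filter(Negate(is.null),
                x[c("patient_ids", "instance_uids", "accession_numbers",
                    "modalities", "time_from", "time_to")])
  cat("<qr_query>", x$level, "level;",
      if (length(sel)) paste(names(sel), collapse = ", ") else "allow-all", "\n")
  invisible(x)
}

validate_qr_query <- function(q) {
  has_selector <- !all(vapply(q[c("patient_ids", "instance_uids",
                                  "accession_numbers", "modalities",
                                  "time_from", "time_to")], is.null, logical(1)))
  if (!has_selector && !q$allow_all)
    stop("query has no selector; set allow_all = TRUE for an unrestricted query",
         call. = FALSE)
  if (!is.null(q$time_from) && !is.null(q$time_to) && q$time_from > q$time_to)
    stop("time_from must not be after time_to", call. = FALSE)
  invisible(q)
}

#' Find matching records at a query level (restricted headers)
#'
#' Executes the query through the provider and returns one record per
#' matching entity at the requested level. Every returned attribute is a
#' member of the restricted header whitelist ([basic_header_keys()]);
#' extended attributes present in the underlying files are never
#' exposed by a find. Results are ordered deterministically by patient,
#' study, series and instance number.
#'
#' @param provider A `qr_provider`.
#' @param query A `qr_query`.
#' @return data.table of restricted headers (zero rows if nothing
#'   matches).
#' @export
qr_find <- function(provider, query) {
  stopifnot(inherits(provider, "qr_provider"))
  validate_qr_query(query)
  filters <- query[c("patient_ids", "instance_uids", "accession_numbers",
                     "modalities", "time_from", "time_to")]
  res <- tryCatch(provider$find(query$level, filters),
                  error = function(e) stop("provider failure for ",
                                           format(query), ": ",
                                           conditionMessage(e), call. = FALSE))
  res <- as.data.table(res)
  extra <- setdiff(names(res), basic_header_keys())
  if (length(extra)) res[, (extra) := NULL]
  ord <- intersect(c("PatientID", "StudyInstanceUID", "SeriesInstanceUID",
                     "InstanceNumber"), names(res))
  if (length(ord)) setorderv(res, ord)
  res[]
}

#' Rate limit configuration for retrievals
#'
#' A fixed-window limiter: at most `max_per_minute` retrieval starts per
#' 60-second window, enforced through the injected clock (so production
#' use throttles in real time while tests drive a simulated clock).
#' Retrieval throttling protects the production PACS from bulk-download
#' pressure; it is off by default.
#'
#' @param max_per_minute Positive number of retrievals allowed per minute.
#' @return Object of class `throttle_config`.
#' @export
throttle_config <- function(max_per_minute) {
  stopifnot(is.numeric(max_per_minute), max_per_minute > 0)
  structure(list(max_per_minute = max_per_minute), class = "throttle_config")
}

#' Wall clock / simulated clock
#'
#' `real_clock()` reads `Sys.time()` and sleeps for real;
#' `sim_clock()` keeps virtual time that only advances on `sleep`,
#' making throttling and session expiry testable without waiting.
#'
#' @param start Numeric start time (seconds) for the simulated clock.
#' @return List with `now()` and `sleep(seconds)`.
#' @export
real_clock <- function() {
  list(now = function() as.numeric(Sys.time()),
       sleep = function(s) Sys.sleep(s))
}

#' @rdname real_clock
#' @export
sim_clock <- function(start = 0) {
  t <- new.env(parent = emptyenv())
  t$now <- start
  list(now = function() t$now,
       sleep = function(s) t$now <- t$now + s)
}

#' Retrieve full data sets by identifier
#'
#' Resolves the given identifiers to SOP instances -- SOP instance UIDs
#' directly, series or study instance UIDs by expansion to all their
#' images -- and retrieves the complete data sets including attributes
#' absent from find responses. Unknown identifiers are collected, not
#' fatal: remaining items are still processed.
#'
#' @param provider A `qr_provider`.
#' @param identifiers Character vector of SOP/series/study instance UIDs.
#' @param throttle Optional [throttle_config()].
#' @param clock Clock used for throttling (see [real_clock()]).
#' @return List of `dicom_record`s; attributes `not_found` (identifiers
#'   that resolved to nothing) and `timestamps` (retrieval start times).
#' @export
qr_retrieve <- function(provider, identifiers, throttle = NULL,
                        clock = real_clock()) {
  stopifnot(inherits(provider, "qr_provider"))
  if (length(identifiers) == 0L)
    return(structure(list(), not_found = character(), timestamps = numeric()))
  # expand series/study identifiers to SOP instances
  img <- provider$find("image", list(instance_uids = identifiers))
  sops <- img$SOPInstanceUID
  direct_missing <- setdiff(identifiers,
                            unique(c(img$SOPInstanceUID, img$SeriesInstanceUID,
                                     img$StudyInstanceUID)))
  window_start <- NULL
  in_window <- 0L
  timestamps <- numeric(length(sops))
  records <- vector("list", length(sops))
  for (i in seq_along(sops)) {
    if (!is.null(throttle)) {
      now <- clock$now()
      if (is.null(window_start) || now - window_start >= 60) {
        window_start <- now
        in_window <- 0L
      }
      if (in_window >= throttle$max_per_minute) {
        clock$sleep(60 - (now - window_start))
        window_start <- clock$now()
        in_window <- 0L
      }
      in_window <- in_window + 1L
    }
    timestamps[i] <- clock$now()
    got <- provider$retrieve(sops[i])
    records[[i]] <- if (length(got$records)) {
      structure(got$records[[1L]], class = "dicom_record")
    } else NULL
    if (length(got$not_found)) direct_missing <- c(direct_missing, got$not_found)
  }
  keep <- !vapply(records, is.null, logical(1))
  structure(records[keep], not_found = unique(direct_missing),
            timestamps = timestamps[keep])
}

#' @export
print.dicom_record <- function(x, ...) {
  cat("<dicom_record>", x$sop_uid, "-", x$attrs$Modality %||% "?",
      format(x$payload_bytes), "bytes\n")
  invisible(x)
}

#' Select images of a series for extraction
#'
#' `"all"` returns every image ordered by InstanceNumber; `"first"`
#' the single image with the minimal InstanceNumber; `"middle"` the
#' image at position `ceiling(n/2)` in InstanceNumber order. Ties and
#' missing InstanceNumbers fall back to lexical SOPInstanceUID order;
#' a fallback is flagged on the result.
#'
#' @param series_images data.table/data.frame of image records of one
#'   series, with `InstanceNumber` and `SOPInstanceUID` columns.
#' @param method One of `"all"`, `"first"`, `"middle"`.
#' @return The selected row(s), with attribute `instance_number_fallback`
#'   set when lexical order was used.
#' @export
select_images <- function(series_images, method = c("all", "first", "middle")) {
  method <- match.arg(method)
  d <- as.data.table(series_images)
  if (nrow(d) == 0L) stop("select_images: empty series", call. = FALSE)
  fallback <- is.null(d$InstanceNumber) || anyNA(d$InstanceNumber)
  inum <- if (fallback) rep(NA_integer_, nrow(d)) else d$InstanceNumber
  ord <- order(inum, d$SOPInstanceUID, na.last = TRUE)
  d <- d[ord, ]
  out <- switch(method,
    all = d,
    first = d[1L, ],
    middle = d[ceiling(nrow(d) / 2), ])
  attr(out, "instance_number_fallback") <- fallback
  out
}
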