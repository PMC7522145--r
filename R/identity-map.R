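# Transient identity mapping between PACS identifiers and research
# pseudonyms. The identity service itself is an external trusted party
# that persists the mapping table; this package's side only ever holds
# a TransientMap scoped to one query, released (and leak-checked) when
# the query completes. The reference connector is an in-process
# keyed-HMAC pseudonymizer so builds are self-contained; a table-backed
# connector serves tests and the contract is the seam for a real
# identity-management service.

.map_registry <- new.env(parent = emptyenv())
.map_registry$live <- 0L

#' An identifier with its namespace
#'
#' Identifier namespaces ("kinds") are resolved independently: a
#' patient identifier, an instance UID and an accession number each map
#' within their own namespace.
#'
#' @param kind One of `"patient"`, `"instance_uid"`, `"accession_number"`.
#' @param value Non-empty identifier string.
#' @return Object of class `id_scope`.
#' @export
id_scope <- function(kind = c("patient", "instance_uid", "accession_number"),
                     value) {
  kind <- match.arg(kind)
  stopifnot(is.character(value), length(value) == 1L, nzchar(value))
  structure(list(kind = kind, value = value), class = "id_scope")
}

.uid_pseudonym <- function(hex) {
  # a valid, deterministic UID under the uuid-derived arc
  d1 <- strtoi(substr(hex, 1, 7), 16L)
  d2 <- strtoi(substr(hex, 8, 14), 16L)
  d3 <- strtoi(substr(hex, 15, 21), 16L)
  paste0("2.25.", d1, ".", d2, ".", d3)
}

.format_pseudonym <- function(kind, hex) {
  switch(kind,
    patient = paste0("PSN-", substr(hex, 1, 16)),
    accession_number = paste0("ACC-", substr(hex, 1, 16)),
    instance_uid = .uid_pseudonym(hex))
}

#' Keyed-HMAC identity connector
#'
#' Pseudonymizes identifiers with HMAC-SHA-256 under a site secret:
#' the same identifier always yields the same pseudonym (enabling
#' stable joins in the warehouse) and pseudonyms are infeasible to
#' reverse without the secret. The connector retains the mapping table
#' it produces -- that table models the trusted third party's store and
#' supports reverse resolution; the extraction pipeline itself only
#' holds [to_pacs_ids()]/[to_pseudonyms()] results transiently.
#' Patient pseudonyms look like `PSN-<16 hex>`, accession pseudonyms
#' `ACC-<16 hex>`, and instance-UID pseudonyms are themselves valid
#' UIDs under the uuid-derived `2.25` arc so they can be written back
#' into DICOM files. A pseudonym collision between distinct identifiers
#' is detected and fatal.
#'
#' @param secret Site secret string.
#' @return Object of class `id_connector`.
#' @export
hmac_connector <- function(secret) {
  stopifnot(is.character(secret), nzchar(secret))
  tab <- new.env(parent = emptyenv())   # kind|value -> pseudonym and reverse
  pseudonymize <- function(kind, values) {
    vapply(values, function(v) {
      # already a pseudonym of this kind: return unchanged (makes
      # pseudonymization, and hence anonymization, idempotent)
      if (!is.null(tab[[paste0("r|", kind, "|", v)]])) return(v)
      hex <- digest::hmac(secret, paste0(kind, "\x1f", v), algo = "sha256")
      psn <- .format_pseudonym(kind, hex)
      fwd <- paste0("f|", kind, "|", v)
      rev <- paste0("r|", kind, "|", psn)
      prev <- tab[[rev]]
      if (!is.null(prev) && !identical(prev, v))
        stop("pseudonym collision within kind '", kind, "'", call. = FALSE)
      tab[[fwd]] <- psn
      tab[[rev]] <- v
      psn
    }, character(1), USE.NAMES = FALSE)
  }
  resolve <- function(kind, pseudonyms) {
    vapply(pseudonyms, function(p) {
      v <- tab[[paste0("r|", kind, "|", p)]]
      if (is.null(v)) NA_character_ else v
    }, character(1), USE.NAMES = FALSE)
  }
  structure(list(pseudonymize = pseudonymize, resolve = resolve),
            class = "id_connector")
}

#' Table-backed identity connector
#'
#' Resolves from a fixed mapping table; identifiers absent from the
#' table are unresolvable in either direction. Intended for tests and
#' for sites that pre-provision pseudonym lists.
#'
#' @param table data.frame with columns `kind`, `value`, `pseudonym`.
#' @return Object of class `id_connector`.
#' @export
table_connector <- function(table) {
  stopifnot(all(c("kind", "value", "pseudonym") %in% names(table)))
  tab <- as.data.table(table)
  if (anyDuplicated(tab[, c("kind", "pseudonym")]))
    stop("pseudonym collision in connector table", call. = FALSE)
  pseudonymize <- function(kind, values) {
    i <- match(paste0(kind, "|", values), paste0(tab$kind, "|", tab$value))
    out <- tab$pseudonym[i]
    already <- is.na(out) & paste0(kind, "|", values) %in%
      paste0(tab$kind, "|", tab$pseudonym)
    out[already] <- values[already]
    out
  }
  resolve <- function(kind, pseudonyms) {
    i <- match(paste0(kind, "|", pseudonyms), paste0(tab$kind, "|", tab$pseudonym))
    tab$value[i]
  }
  structure(list(pseudonymize = pseudonymize, resolve = resolve),
            class = "id_connector")
}

#' Pseudonymizer function view of a connector
#'
#' Adapts a connector to the `(kind, value) -> pseudonym` function
#' consumed by [anonymize()].
#'
#' @param connector An `id_connector`.
#' @return Function of `(kind, value)`.
#' @export
connector_pseudonymizer <- function(connector) {
  function(kind, value) connector$pseudonymize(kind, value)
}

.new_transient_map <- function(pairs, unresolved, direction) {
  m <- new.env(parent = emptyenv())
  m$pairs <- pairs
  m$unresolved <- unresolved
  m$direction <- direction
  m$released <- FALSE
  m$created <- as.numeric(Sys.time())
  .map_registry$live <- .map_registry$live + 1L
  class(m) <- "transient_map"
  m
}

.resolve_batch <- function(connector, scopes, forward) {
  if (inherits(scopes, "id_scope")) scopes <- list(scopes)
  stopifnot(all(vapply(scopes, inherits, logical(1), "id_scope")))
  kinds <- vapply(scopes, `[[`, character(1), "kind")
  values <- vapply(scopes, `[[`, character(1), "value")
  out <- character(length(values))
  for (k in unique(kinds)) {
    i <- which(kinds == k)
    res <- tryCatch(
      if (forward) connector$pseudonymize(k, values[i])
      else connector$resolve(k, values[i]),
      error = function(e) stop("identity connector failure: ",
                               conditionMessage(e), call. = FALSE))
    out[i] <- res
  }
  ok <- !is.na(out)
  if (forward) {
    pairs <- data.table(kind = kinds[ok], pacs_id = values[ok],
                        pseudonym = out[ok])
  } else {
    pairs <- data.table(kind = kinds[ok], pacs_id = out[ok],
                        pseudonym = values[ok])
  }
  .new_transient_map(pairs, unresolved = values[!ok],
                     direction = if (forward) "to_pseudonyms" else "to_pacs_ids")
}

#' Resolve pseudonyms to PACS identifiers (transiently)
#'
#' Builds a [transient map][release_map] holding one PACS identifier
#' per resolvable pseudonym; unresolvable pseudonyms are listed under
#' `map_unresolved()`, never fabricated. A connector failure raises a
#' transport error and no partial map is created.
#'
#' @param connector An `id_connector`.
#' @param scopes An [id_scope()] or list of them, carrying pseudonyms.
#' @return A `transient_map`.
#' @export
to_pacs_ids <- function(connector, scopes) .resolve_batch(connector, scopes, FALSE)

#' Resolve PACS identifiers to pseudonyms (transiently)
#'
#' Mirror of [to_pacs_ids()].
#'
#' @inheritParams to_pacs_ids
#' @return A `transient_map`.
#' @export
to_pseudonyms <- function(connector, scopes) .resolve_batch(connector, scopes, TRUE)

.check_live <- function(map) {
  stopifnot(inherits(map, "transient_map"))
  if (map$released) stop("transient map has been released", call. = FALSE)
}

#' Look up within a transient map
#'
#' @param map A `transient_map`.
#' @param pseudonym,pacs_id Identifier to look up (scoped by `kind`).
#' @param kind Identifier namespace.
#' @return The mapped identifier; error if absent or the map was
#'   released.
#' @export
map_pacs_id <- function(map, pseudonym, kind = "patient") {
  .check_live(map)
  i <- which(map$pairs$kind == kind & map$pairs$pseudonym == pseudonym)
  if (length(i) != 1L) stop("not found in transient map: ", pseudonym,
                            call. = FALSE)
  map$pairs$pacs_id[i]
}

#' @rdname map_pacs_id
#' @export
map_pseudonym <- function(map, pacs_id, kind = "patient") {
  .check_live(map)
  i <- which(map$pairs$kind == kind & map$pairs$pacs_id == pacs_id)
  if (length(i) != 1L) stop("not found in transient map", call. = FALSE)
  map$pairs$pseudonym[i]
}

#' @rdname map_pacs_id
#' @export
map_size <- function(map) {
  .check_live(map)
  nrow(map$pairs)
}

#' @rdname map_pacs_id
#' @export
map_unresolved <- function(map) {
  .check_live(map)
  map$unresolved
}

#' Release a transient map
#'
#' Destroys the pseudonym/identifier pairs; afterwards every accessor
#' raises an error. Double release is a no-op. The number of live maps
#' is observable through [live_transient_maps()] so workloads can assert
#' they leak none.
#'
#' @param map A `transient_map`.
#' @return `NULL`, invisibly.
#' @export
release_map <- function(map) {
  stopifnot(inherits(map, "transient_map"))
  if (!map$released) {
    map$pairs <- NULL
    map$unresolved <- NULL
    map$released <- TRUE
    .map_registry$live <- .map_registry$live - 1L
  }
  invisible(NULL)
}

#' @rdname release_map
#' @export
live_transient_maps <- function() .map_registry$live

#' @export
print.transient_map <- function(x, ...) {
  if (x$released) cat("<transient_map> released\n")
  else cat("<transient_map>", nrow(x$pairs), "pairs,",
           length(x$unresolved), "unresolved\n")
  invisible(x)
}
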