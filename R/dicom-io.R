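# Minimal DICOM Part 10 codec, explicit VR little endian only.
# Covers the attribute subset in `.dicom_dict`; unknown elements are
# preserved by tag on read. This is deliberately not a general DICOM
# implementation: no sequences, no implicit VR, no compressed transfer
# syntaxes -- the synthetic PACS writes none of those.

.TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
.IMPLEMENTATION_CLASS_UID <- "1.3.6.1.4.1.99999.2.1"
.LONG_FORM_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
.u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
.read_u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.read_u32 <- function(raw4) {
  sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
}

.pad_even <- function(bytes, pad) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.encode_value <- function(vr, value) {
  if (vr %in% c("OB", "OW")) {
    stopifnot(is.raw(value))
    return(.pad_even(value, as.raw(0L)))
  }
  if (vr %in% c("US", "UL")) {
    v <- as.numeric(value)
    sz <- if (vr == "US") 2L else 4L
    enc <- if (vr == "US") lapply(v, .u16) else lapply(v, .u32)
    return(do.call(c, enc))
  }
  s <- paste(as.character(value), collapse = "\\")
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  .pad_even(charToRaw(s), pad)
}

.encode_element <- function(group, element, vr, value) {
  body <- .encode_value(vr, value)
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% .LONG_FORM_VRS) {
    c(head, as.raw(c(0L, 0L)), .u32(length(body)), body)
  } else {
    if (length(body) > 65534L) stop("value too long for short-form VR ", vr)
    c(head, .u16(length(body)), body)
  }
}

#' Write a DICOM Part 10 file
#'
#' Serializes a flat attribute set (named by DICOM keyword) and an
#' optional pixel payload as a Part 10 file with a standard 128-byte
#' preamble, file meta information group and explicit VR little endian
#' data set.
#'
#' @param path Output file path.
#' @param attrs Named list of attribute values; names must be keywords
#'   from the shipped dictionary (e.g. `PatientID`, `StudyInstanceUID`).
#'   Multi-valued attributes are passed as vectors and joined with the
#'   DICOM value separator.
#' @param pixel Optional raw vector written as `PixelData` (OW).
#' @return `path`, invisibly.
#' @export
dcm_write <- function(path, attrs, pixel = NULL) {
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  if (is.null(attrs$SOPClassUID)) attrs$SOPClassUID <- .SOP_CLASS_SECONDARY_CAPTURE
  if (is.null(attrs$SOPInstanceUID)) stop("SOPInstanceUID is required")
  dict <- .dict_by_keyword(names(attrs))
  ord <- order(dict$group, dict$element)
  body <- vector("list", length(ord) + 1L)
  k <- 1L
  for (i in ord) {
    body[[k]] <- .encode_element(dict$group[i], dict$element[i], dict$vr[i],
                                 attrs[[dict$keyword[i]]])
    k <- k + 1L
  }
  if (!is.null(pixel)) {
    body[[k]] <- .encode_element(0x7FE0L, 0x0010L, "OW", pixel)
  }
  body <- do.call(c, body[!vapply(body, is.null, logical(1))])

  meta <- c(
    .encode_element(2L, 1L, "OB", as.raw(c(0L, 1L))),
    .encode_element(2L, 2L, "UI", attrs$SOPClassUID),
    .encode_element(2L, 3L, "UI", attrs$SOPInstanceUID),
    .encode_element(2L, 16L, "UI", .TRANSFER_SYNTAX_EXPLICIT_LE),
    .encode_element(2L, 18L, "UI", .IMPLEMENTATION_CLASS_UID)
  )
  out <- c(raw(128L), charToRaw("DICM"),
           .encode_element(2L, 0L, "UL", length(meta)), meta, body)
  writeBin(out, path, useBytes = TRUE)
  invisible(path)
}

.decode_value <- function(vr, bytes) {
  if (vr %in% c("OB", "OW", "UN")) return(bytes)
  if (vr == "US") {
    n <- length(bytes) %/% 2L
    return(vapply(seq_len(n), function(i) .read_u16(bytes[(2L * i - 1L):(2L * i)]),
                  integer(1)))
  }
  if (vr == "UL") {
    n <- length(bytes) %/% 4L
    return(vapply(seq_len(n), function(i) .read_u32(bytes[(4L * i - 3L):(4L * i)]),
                  numeric(1)))
  }
  s <- rawToChar(bytes[bytes != as.raw(0L)])
  s <- sub("[ ]+$", "", s)
  if (vr == "IS") return(as.integer(strsplit(s, "\\\\")[[1]]))
  if (vr == "DS") return(as.numeric(strsplit(s, "\\\\")[[1]]))
  s
}

#' Read a DICOM Part 10 file
#'
#' Parses a Part 10 file written in explicit VR little endian. Elements
#' found in the shipped dictionary are returned under their keyword;
#' unknown elements under their `"gggg,eeee"` tag.
#'
#' @param path File path.
#' @param include_pixel If `FALSE`, `PixelData` bytes are dropped (its
#'   byte length is still reported).
#' @return A list with `attrs` (named list), `pixel` (raw or `NULL`),
#'   `pixel_bytes` and `path`.
#' @export
dcm_read <- function(path, include_pixel = TRUE) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  pos <- 133L
  n <- length(bytes)
  attrs <- list()
  pixel <- NULL
  pixel_bytes <- 0
  while (pos + 7L <= n) {
    group <- .read_u16(bytes[pos:(pos + 1L)])
    element <- .read_u16(bytes[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_FORM_VRS) {
      len <- .read_u32(bytes[(pos + 8L):(pos + 11L)])
      pos <- pos + 12L
    } else {
      len <- .read_u16(bytes[(pos + 6L):(pos + 7L)])
      pos <- pos + 8L
    }
    val_bytes <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0L)
    pos <- pos + len
    if (group == 2L) next  # file meta: transfer syntax is fixed here
    tag <- sprintf("%04X,%04X", group, element)
    i <- match(tag, .dicom_dict$tag)
    key <- if (is.na(i)) tag else .dicom_dict$keyword[i]
    if (key == "PixelData") {
      pixel_bytes <- len
      if (include_pixel) pixel <- val_bytes
      next
    }
    attrs[[key]] <- .decode_value(vr, val_bytes)
  }
  list(attrs = attrs, pixel = pixel, pixel_bytes = pixel_bytes, path = path)
}
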