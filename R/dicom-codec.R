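# Minimal DICOM Part-10 codec: explicit VR little endian, flat datasets
# (no sequences), enough of the standard to carry MR acquisition metadata
# plus a Siemens-style private block and a token pixel payload. The scan
# readers and the synthetic generator both sit on top of this; nothing here
# attempts to read compressed transfer syntaxes or implicit VR.

u16le <- function(x) as.raw(c(bitwAnd(x, 0xFF), bitwAnd(bitwShiftR(x, 8), 0xFF)))
u32le <- function(x) {
  as.raw(c(bitwAnd(x, 0xFF), bitwAnd(bitwShiftR(x, 8), 0xFF),
           bitwAnd(bitwShiftR(x, 16), 0xFF), bitwAnd(bitwShiftR(x, 24), 0xFF)))
}
rd_u16le <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
rd_u32le <- function(b, i) {
  as.integer(b[i]) + 256 * as.integer(b[i + 1L]) +
    65536 * as.integer(b[i + 2L]) + 16777216 * as.integer(b[i + 3L])
}

long_vrs <- c("OB", "OW", "OF", "UN", "SQ", "UT")

encode_value <- function(vr, value) {
  if (vr == "US") return(writeBin(as.integer(value), raw(), size = 2, endian = "little"))
  if (vr == "UL") return(writeBin(as.integer(value), raw(), size = 4, endian = "little"))
  if (vr %in% c("OB", "UN")) {
    b <- if (is.character(value)) charToRaw(value) else as.raw(value)
    if (length(b) %% 2L) b <- c(b, as.raw(0))
    return(b)
  }
  s <- paste(vapply(value, function(v) {
    if (is.numeric(v)) format(v, trim = TRUE, digits = 15, scientific = FALSE)
    else as.character(v)
  }, ""), collapse = "\\")
  b <- charToRaw(s)
  if (length(b) %% 2L) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
  b
}

dcm_element <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

encode_element <- function(el) {
  bytes <- encode_value(el$vr, el$value)
  head <- c(u16le(el$group), u16le(el$element), charToRaw(el$vr))
  if (el$vr %in% long_vrs) {
    c(head, as.raw(c(0, 0)), u32le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534L) stop("value too long for short VR ", el$vr)
    c(head, u16le(length(bytes)), bytes)
  }
}

#' Write a flat DICOM Part-10 file (explicit VR little endian)
#'
#' @param path output file.
#' @param elements list of elements built with `dcm_element(group, element,
#'   vr, value)`; group 0002 is generated internally and must not appear.
#' @param sop_instance_uid UID recorded in the file meta header.
#' @return `path`, invisibly.
#' @keywords internal
dicom_write <- function(path, elements, sop_instance_uid) {
  groups <- vapply(elements, `[[`, 0, "group")
  if (any(groups == 0x0002L)) stop("file meta group is generated internally")
  meta <- list(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002L, 0x0002L, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    dcm_element(0x0002L, 0x0003L, "UI", sop_instance_uid),
    dcm_element(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0002L, 0x0012L, "UI", "1.2.826.0.1.3680043.9999.1")
  )
  meta_bytes <- do.call(c, lapply(meta, encode_element))
  # dataset elements in ascending tag order, as the standard requires
  ord <- order(groups, vapply(elements, `[[`, 0, "element"))
  data_bytes <- do.call(c, lapply(elements[ord], encode_element))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(encode_element(dcm_element(0x0002L, 0x0000L, "UL", length(meta_bytes))), con)
  writeBin(meta_bytes, con)
  writeBin(data_bytes, con)
  invisible(path)
}

#' Test whether a file is DICOM Part-10
#'
#' Extension-agnostic: checks the 128-byte preamble + "DICM" magic.
#'
#' @param path file path.
#' @return logical scalar.
#' @keywords internal
is_dicom_file <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 132) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 132L)
  length(head) == 132L && rawToChar(head[129:132]) == "DICM"
}

#' Read a flat DICOM Part-10 file
#'
#' Parses an explicit-VR little-endian dataset into a named list keyed
#' `"GGGG,EEEE"`, each entry holding `vr` and the raw value bytes. Stops
#' after PixelData. Any structural problem (bad magic, unsupported transfer
#' syntax, malformed element) raises an error; tree scanners catch it and
#' skip the file.
#'
#' @param path file path.
#' @return Named list of `list(vr, bytes)`.
#' @keywords internal
dicom_read <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 132) stop("not a DICOM file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  b <- readBin(con, "raw", sz)
  if (rawToChar(b[129:132]) != "DICM") stop("missing DICM magic: ", path)
  i <- 133L
  n <- length(b)
  out <- list()
  while (i + 7L <= n) {
    group <- rd_u16le(b, i); elem <- rd_u16le(b, i + 2L)
    vr <- rawToChar(b[(i + 4L):(i + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) stop("malformed element at offset ", i)
    if (vr %in% long_vrs) {
      if (i + 11L > n) stop("truncated element header")
      len <- rd_u32le(b, i + 8L); i <- i + 12L
    } else {
      len <- rd_u16le(b, i + 6L); i <- i + 8L
    }
    if (i + len - 1L > n) stop("element value runs past end of file")
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, bytes = if (len > 0L) b[i:(i + len - 1L)] else raw(0))
    i <- i + len
    if (group == 0x7FE0L && elem == 0x0010L) break
  }
  ts <- dcm_string(out, "0002,0010")
  if (!is.na(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax '", ts, "' in ", path)
  out
}

dcm_string <- function(ds, key) {
  el <- ds[[key]]
  if (is.null(el) || !length(el$bytes)) return(NA_character_)
  s <- rawToChar(el$bytes[el$bytes != as.raw(0)])
  trimws(s)
}

dcm_numeric <- function(ds, key) {
  s <- dcm_string(ds, key)
  if (is.na(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\", fixed = FALSE)[[1]])
}

dcm_tokens <- function(ds, key) {
  s <- dcm_string(ds, key)
  if (is.na(s)) return(NULL)
  trimws(strsplit(s, "\\\\")[[1]])
}
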