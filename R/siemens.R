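# Siemens private-header support. Siemens scanners embed an ASCII protocol
# dump ("ASCCONV" block) in the CSA series header; it carries settings with
# no public DICOM tag, notably the shim adjustment mode, the parallel
# imaging (iPAT) mode and the multi-slice mode. GE and Philips private
# headers use undocumented binary layouts and are deliberately skipped: runs
# from those vendors simply lack these parameters.

ascconv_begin <- "### ASCCONV BEGIN ###"
ascconv_end <- "### ASCCONV END ###"

shim_mode_codes <- c("0x1" = "tune_up", "0x2" = "standard", "0x20" = "advanced")
pat_mode_codes <- c("0x1" = "none", "0x2" = "GRAPPA", "0x3" = "mSENSE")
multislice_codes <- c("0x1" = "sequential", "0x2" = "interleaved", "0x4" = "single-shot")

decode_code <- function(code, map) {
  if (code %in% names(map)) unname(map[[code]]) else paste0("code_", code)
}
encode_code <- function(token, map) {
  i <- match(token, map)
  if (is.na(i)) stop("no ASCCONV code for token '", token, "'")
  names(map)[i]
}

# Render an ASCCONV text block for the synthetic generator.
ascconv_block <- function(shim_mode = NULL, parallel_imaging = NULL,
                          multi_slice_mode = NULL) {
  lines <- c(ascconv_begin)
  if (!is.null(shim_mode))
    lines <- c(lines, paste0("sAdjData.uiAdjShimMode\t = ",
                             encode_code(shim_mode, shim_mode_codes)))
  if (!is.null(parallel_imaging))
    lines <- c(lines, paste0("sPat.ucPATMode\t = ",
                             encode_code(parallel_imaging, pat_mode_codes)))
  if (!is.null(multi_slice_mode))
    lines <- c(lines, paste0("sKSpace.ucMultiSliceMode\t = ",
                             encode_code(multi_slice_mode, multislice_codes)))
  paste(c(lines, ascconv_end), collapse = "\n")
}

#' Parse a Siemens-style private header block
#'
#' Extracts shim mode, parallel imaging (iPAT) mode and multi-slice mode
#' from the ASCII ASCCONV block of a Siemens CSA series header. A missing,
#' truncated or malformed block yields an empty map (the parameters then
#' participate only in missing-parameter reporting); this function never
#' throws. GE/Philips private headers are not decoded.
#'
#' @param x raw vector or character scalar holding the private header
#'   payload.
#' @return Named list of [param_value()] objects with
#'   `source = "private-header"`; possibly empty.
#' @export
parse_siemens_private <- function(x) {
  txt <- tryCatch({
    if (is.raw(x)) rawToChar(x[x != as.raw(0)]) else as.character(x)
  }, error = function(e) "")
  if (!length(txt) || is.na(txt)) txt <- ""
  beg <- regexpr(ascconv_begin, txt, fixed = TRUE)
  if (beg < 0) return(list())
  fin <- regexpr(ascconv_end, txt, fixed = TRUE)
  if (fin < 0 || fin < beg) {
    warning("truncated ASCCONV block; private parameters skipped")
    return(list())
  }
  body <- substr(txt, beg + nchar(ascconv_begin), fin - 1L)
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) next
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  out <- list()
  if (!is.null(kv[["sAdjData.uiAdjShimMode"]]))
    out$ShimMode <- param_value("ShimMode",
      decode_code(kv[["sAdjData.uiAdjShimMode"]], shim_mode_codes),
      source = "private-header")
  if (!is.null(kv[["sPat.ucPATMode"]]))
    out$ParallelImaging <- param_value("ParallelImaging",
      decode_code(kv[["sPat.ucPATMode"]], pat_mode_codes),
      source = "private-header")
  if (!is.null(kv[["sKSpace.ucMultiSliceMode"]]))
    out$MultiSliceMode <- param_value("MultiSliceMode",
      decode_code(kv[["sKSpace.ucMultiSliceMode"]], multislice_codes),
      source = "private-header")
  out
}
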