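#' Construct a reference protocol
#'
#' The expected value for each audited parameter of one modality, either
#' supplied externally (e.g. an XML export from the scanner) or inferred
#' from the data by majority vote (see [infer_reference()]).
#'
#' @param modality_label normalized modality label.
#' @param entries named list of [param_value()] objects.
#' @param source `"inferred"` or `"external"`.
#' @param support named integer vector: for inferred references, how many
#'   runs agreed with the modal value of each parameter.
#' @return An object of class `mrc_reference`.
#' @export
reference_protocol <- function(modality_label, entries,
                               source = c("inferred", "external"),
                               support = integer()) {
  source <- match.arg(source)
  nms <- vapply(entries, `[[`, "", "name")
  names(entries) <- nms
  if (source == "inferred" && length(support) && any(support < 1L))
    stop("inferred reference entries must have support >= 1")
  structure(list(modality_label = modality_label, entries = entries,
                 source = source, support = support),
            class = "mrc_reference")
}

#' @export
print.mrc_reference <- function(x, ...) {
  cat(sprintf("<mrc_reference '%s' (%s): %d parameters>\n",
              x$modality_label, x$source, length(x$entries)))
  invisible(x)
}

#' Read a reference protocol from a flat XML export
#'
#' Expected schema:
#' `<protocol modality="..."><param name="..." value="..." units="..."/></protocol>`
#' (a generic flat key-value export; vendor-proprietary binary protocol
#' formats are out of scope). Parameter names outside the controlled
#' vocabulary are retained and flagged unknown. Numeric-kind values are
#' parsed as numbers; backslash-separated values become multivalued tuples.
#'
#' @param path XML file.
#' @return An `mrc_reference` with `source = "external"`.
#' @export
read_reference_xml <- function(path) {
  if (!file.exists(path)) stop("reference protocol file not found: ", path)
  doc <- xml2::read_xml(path)
  modality <- xml2::xml_attr(doc, "modality")
  if (is.na(modality)) modality <- ""
  nodes <- xml2::xml_find_all(doc, ".//param")
  entries <- list()
  for (nd in nodes) {
    nm <- xml2::xml_attr(nd, "name")
    raw <- xml2::xml_attr(nd, "value")
    ve <- vocab_entry(nm)
    val <- if (grepl("\\\\", raw)) {
      parts <- strsplit(raw, "\\\\")[[1]]
      nums <- suppressWarnings(as.numeric(parts))
      if (!anyNA(nums)) nums else parts
    } else if (!is.null(ve) && ve$kind == "numeric") {
      as.numeric(raw)
    } else if (is.null(ve) && !is.na(suppressWarnings(as.numeric(raw)))) {
      as.numeric(raw)
    } else raw
    entries[[nm]] <- param_value(nm, val, source = "standard-tag")
  }
  reference_protocol(normalize_label(modality), entries, source = "external")
}

#' Write a reference protocol to flat XML
#'
#' Inverse of [read_reference_xml()]: a protocol written and re-read
#' compares equal entry-by-entry.
#'
#' @param ref an `mrc_reference`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_xml <- function(ref, path) {
  stopifnot(inherits(ref, "mrc_reference"))
  doc <- xml2::xml_new_root("protocol", modality = ref$modality_label)
  for (nm in sort(names(ref$entries))) {
    p <- ref$entries[[nm]]
    if (!p$present) next
    xml2::xml_add_child(doc, "param", name = nm,
                        value = format_param_value(p), units = p$units)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
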