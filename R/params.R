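#' Construct a parameter value
#'
#' The atom of the compliance model: one named acquisition parameter with its
#' value, kind, units and provenance. Kind and units come from the controlled
#' vocabulary ([param_vocabulary()]); names outside the vocabulary are
#' retained (kind guessed from the value) and marked unknown so external
#' reference protocols with extra entries survive a round trip.
#'
#' @param name parameter name (vocabulary string, e.g. `"RepetitionTime"`).
#' @param value scalar number, string token, or vector (multivalued); `NULL`
#'   for an absent parameter.
#' @param source one of `"standard-tag"`, `"private-header"`, `"sidecar"`.
#' @param present logical; `FALSE` means the parameter was expected but not
#'   found, in which case `value` must be `NULL`.
#' @return An object of class `mrc_param`.
#' @export
param_value <- function(name, value, source = "standard-tag",
                        present = !is.null(value)) {
  stopifnot(is.character(name), length(name) == 1L)
  source <- match.arg(source, c("standard-tag", "private-header", "sidecar"))
  ve <- vocab_entry(name)
  unknown <- is.null(ve)
  if (unknown) {
    kind <- if (is.numeric(value) && length(value) > 1L) "multivalued"
            else if (is.numeric(value)) "numeric" else "categorical"
    units <- ""
  } else {
    kind <- ve$kind
    units <- ve$units
  }
  if (!present) value <- NULL
  if (present) {
    if (kind == "numeric") {
      value <- as.numeric(value)
      if (length(value) != 1L || !is.finite(value))
        stop("numeric parameter '", name, "' must be a finite scalar")
    } else if (kind == "categorical") {
      value <- as.character(value)
      if (length(value) != 1L || is.na(value))
        stop("categorical parameter '", name, "' must be a single token")
    } else {
      if (is.numeric(value) && !all(is.finite(value)))
        stop("multivalued parameter '", name, "' has non-finite entries")
    }
  }
  structure(
    list(name = name, value = value, kind = kind, units = units,
         source = source, present = isTRUE(present), unknown = unknown),
    class = "mrc_param")
}

#' @export
print.mrc_param <- function(x, ...) {
  cat(sprintf("<%s%s = %s %s [%s]%s>\n", x$name,
              if (x$unknown) "?" else "",
              if (x$present) format_param_value(x) else "<absent>",
              x$units, x$kind, paste0(" src=", x$source)))
  invisible(x)
}

format_param_value <- function(p) {
  if (!p$present || is.null(p$value)) return(NA_character_)
  paste(format(p$value, trim = TRUE, digits = 15), collapse = "\\")
}

# JSON-friendly (de)serialization used by the monitor state cache and the
# debug dump of a hierarchy.
param_to_list <- function(p) {
  list(name = p$name, value = p$value, kind = p$kind, units = p$units,
       source = p$source, present = p$present)
}

param_from_list <- function(l) {
  v <- l$value
  if (!is.null(v) && l$kind == "multivalued") v <- unlist(v)
  param_value(l$name, if (isTRUE(l$present)) v else NULL,
              source = l$source, present = isTRUE(l$present))
}

# Build a named parameter map from a plain named list of raw values.
# NULL entries become present=FALSE placeholders.
params_from_values <- function(values, source = "standard-tag",
                               absent = character()) {
  out <- list()
  for (nm in names(values)) {
    out[[nm]] <- param_value(nm, values[[nm]], source = source)
  }
  for (nm in absent) {
    out[[nm]] <- param_value(nm, NULL, source = source, present = FALSE)
  }
  out
}
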