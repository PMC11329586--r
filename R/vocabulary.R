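#' Controlled vocabulary of audited acquisition parameters
#'
#' Each audited parameter has a fixed kind (numeric, categorical or
#' multivalued), fixed units, a DICOM tag mapping and/or a BIDS sidecar key,
#' and a scale factor that converts the sidecar's native unit to the package
#' unit (e.g. BIDS stores RepetitionTime in seconds; the package works in ms,
#' the DICOM native unit).
#'
#' Parameters whose `tag_group` is `NA` have no public DICOM tag and are read
#' from the Siemens private header (ASCCONV block) when available; parameters
#' whose `sidecar_key` is `NA` are DICOM-only. Sidecar keys without a BIDS
#' standard equivalent (ShimMode, NumberOfSlices, FieldOfView) are this
#' package's documented convention.
#'
#' @return A data.frame with one row per vocabulary entry: `name`, `kind`,
#'   `units`, `tag_group`, `tag_element`, `vr`, `sidecar_key`,
#'   `sidecar_scale`.
#' @export
param_vocabulary <- function() {
  v <- rbind(
    c("RepetitionTime",         "numeric",      "ms",       "0018", "0080", "DS", "RepetitionTime",                "1000"),
    c("EchoTime",               "numeric",      "ms",       "0018", "0081", "DS", "EchoTime",                      "1000"),
    c("FlipAngle",              "numeric",      "degrees",  "0018", "1314", "DS", "FlipAngle",                     "1"),
    c("PhaseEncodingDirection", "categorical",  "",         "0018", "1312", "CS", "PhaseEncodingDirection",        NA),
    c("PixelBandwidth",         "numeric",      "Hz/pixel", "0018", "0095", "DS", "PixelBandwidth",                "1"),
    c("EchoTrainLength",        "numeric",      "",         "0018", "0091", "IS", "EchoTrainLength",               "1"),
    c("PhaseEncodingSteps",     "numeric",      "",         "0018", "0089", "IS", "PhaseEncodingSteps",            "1"),
    c("MagneticFieldStrength",  "numeric",      "T",        "0018", "0087", "DS", "MagneticFieldStrength",         "1"),
    c("SequenceVariant",        "categorical",  "",         "0018", "0021", "CS", "SequenceVariant",               NA),
    c("ShimMode",               "categorical",  "",         NA,     NA,     NA,   "ShimMode",                      NA),
    c("ParallelImaging",        "categorical",  "",         NA,     NA,     NA,   "ParallelAcquisitionTechnique",  NA),
    c("MultiSliceMode",         "categorical",  "",         NA,     NA,     NA,   NA,                              NA),
    c("FieldOfView",            "numeric",      "mm",       "0018", "1100", "DS", "FieldOfView",                   "1"),
    c("NumberOfSlices",         "numeric",      "",         "0020", "1002", "IS", "NumberOfSlices",                "1"),
    c("SliceThickness",         "numeric",      "mm",       "0018", "0050", "DS", "SliceThickness",                "1"),
    c("Angulation",             "multivalued",  "",         "0020", "0037", "DS", "Angulation",                    NA)
  )
  out <- as.data.frame(v, stringsAsFactors = FALSE)
  names(out) <- c("name", "kind", "units", "tag_group", "tag_element", "vr",
                  "sidecar_key", "sidecar_scale")
  out$sidecar_scale <- as.numeric(out$sidecar_scale)
  out
}

vocab_entry <- function(name) {
  v <- param_vocabulary()
  i <- match(name, v$name)
  if (is.na(i)) return(NULL)
  as.list(v[i, ])
}

#' Parameters audited by default in a horizontal audit
#'
#' The default roster covers the parameters most often implicated in
#' protocol drift: timing (TR, TE), excitation (flip angle), sampling
#' (phase encoding direction and steps, echo train length, pixel bandwidth),
#' hardware/sequence identity (field strength, sequence variant) and the
#' subject-specific settings readable from Siemens private headers or BIDS
#' sidecars (shim mode, parallel imaging). Geometry parameters are checked
#' by the vertical audit instead (see [vertical_audit()]).
#'
#' @return Character vector of vocabulary names.
#' @export
default_audit_params <- function() {
  c("RepetitionTime", "EchoTime", "FlipAngle", "PhaseEncodingDirection",
    "PixelBandwidth", "EchoTrainLength", "PhaseEncodingSteps",
    "ShimMode", "ParallelImaging", "SequenceVariant",
    "MagneticFieldStrength")
}

#' Geometry parameters checked by the vertical audit
#' @return Character vector of vocabulary names.
#' @export
geometry_params <- function() {
  c("FieldOfView", "NumberOfSlices", "SliceThickness", "Angulation")
}

# Cross-dialect phase-encoding map: BIDS axis tokens to anatomical tokens
# under an assumed axial acquisition. Applied only when comparing runs read
# from different sources; within one source native tokens are compared as-is.
ped_dialect_map <- c("j-" = "AP", "j" = "PA", "i" = "RL", "i-" = "LR",
                     "k" = "IS", "k-" = "SI")

#' Normalize a phase-encoding token for cross-source comparison
#'
#' Maps BIDS axis/polarity tokens (`i`, `i-`, `j`, `j-`, `k`, `k-`) onto
#' anatomical tokens (`RL`, `LR`, `PA`, `AP`, `IS`, `SI`); anything else is
#' returned unchanged. Only use this when comparing values read from
#' different formats — audits within one format compare native tokens.
#'
#' @param token character scalar.
#' @return character scalar.
#' @export
normalize_ped <- function(token) {
  if (is.null(token) || length(token) != 1L || is.na(token)) return(token)
  if (token %in% names(ped_dialect_map)) unname(ped_dialect_map[[token]]) else token
}

#' Normalize a sequence/protocol name into a modality label
#'
#' Uppercases, collapses runs of whitespace and punctuation to a single
#' underscore and strips leading/trailing underscores, so that e.g.
#' `"func_task-rest_bold"` and `"FUNC task-rest bold"` group together.
#' Grouping is by acquisition sequence, never by file layout.
#'
#' @param x character vector of raw names.
#' @return character vector of normalized labels.
#' @export
normalize_label <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("[^A-Z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}
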