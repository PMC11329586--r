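#' Create an empty dataset hierarchy
#'
#' The central in-memory container: a set of runs (one per acquired series)
#' addressable both modality-first (modality -> subject -> session -> runs,
#' the horizontal-audit traversal) and subject-first (subject -> modality ->
#' runs, the vertical-audit traversal). Both views are derived from the same
#' run set, so they can never disagree; insertion order never matters.
#'
#' @param dataset_name name recorded in reports.
#' @param format `"dicom"` or `"bids"`.
#' @return An object of class `mrc_hierarchy`.
#' @export
new_hierarchy <- function(dataset_name = "unnamed", format = c("dicom", "bids")) {
  format <- match.arg(format)
  structure(list(dataset_name = dataset_name, format = format, runs = list()),
            class = "mrc_hierarchy")
}

#' Construct a run
#'
#' One acquired series: identifiers, vendor, optional echo number and
#' acquisition time, and the map of parameter values keyed by vocabulary
#' name.
#'
#' @param run_id unique series identifier (DICOM SeriesInstanceUID or BIDS
#'   file path).
#' @param subject_id,session_id,modality_label identifiers; the label should
#'   already be normalized via [normalize_label()].
#' @param vendor manufacturer token (e.g. `"SIEMENS"`); `""` if unknown.
#' @param parameters named list of [param_value()] objects.
#' @param echo_number optional integer for multi-echo series.
#' @param entities BIDS entity string (`"task-rest"` etc.), `""` for DICOM.
#' @param acquisition_time optional timestamp string.
#' @param flags character vector of reader flags (e.g. `"missing-sidecar"`).
#' @return An object of class `mrc_run`.
#' @export
new_run <- function(run_id, subject_id, session_id, modality_label,
                    vendor = "", parameters = list(), echo_number = NA_integer_,
                    entities = "", acquisition_time = NA_character_,
                    flags = character()) {
  stopifnot(is.character(run_id), nzchar(run_id))
  nms <- vapply(parameters, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate parameter names in run ", run_id)
  names(parameters) <- nms
  structure(
    list(run_id = run_id, subject_id = subject_id, session_id = session_id,
         modality_label = modality_label, vendor = vendor,
         parameters = parameters, echo_number = echo_number,
         entities = entities, acquisition_time = acquisition_time,
         flags = flags),
    class = "mrc_run")
}

#' Add a run to a hierarchy
#'
#' @param h an `mrc_hierarchy`.
#' @param r an `mrc_run`; its `run_id` must not already be present.
#' @return The updated hierarchy.
#' @export
add_run <- function(h, r) {
  stopifnot(inherits(h, "mrc_hierarchy"), inherits(r, "mrc_run"))
  if (r$run_id %in% names(h$runs))
    stop("duplicate run_id '", r$run_id, "' rejected")
  h$runs[[r$run_id]] <- r
  h
}

run_field <- function(h, field) {
  vapply(h$runs, function(r) as.character(r[[field]]), "")
}

#' Runs for one modality, in deterministic order
#'
#' @param h an `mrc_hierarchy`.
#' @param modality_label normalized label; unknown labels yield an empty
#'   list, not an error.
#' @return List of runs ordered by (subject_id, session_id, run_id).
#' @export
runs_for <- function(h, modality_label) {
  keep <- run_field(h, "modality_label") == modality_label
  rs <- h$runs[keep]
  if (!length(rs)) return(list())
  ord <- order(vapply(rs, `[[`, "", "subject_id"),
               vapply(rs, `[[`, "", "session_id"),
               vapply(rs, `[[`, "", "run_id"))
  unname(rs[ord])
}

#' Modalities acquired for one subject
#'
#' @param h an `mrc_hierarchy`.
#' @param subject_id subject identifier; absent subjects yield an empty
#'   vector.
#' @return Sorted character vector of modality labels.
#' @export
modalities_for <- function(h, subject_id) {
  keep <- run_field(h, "subject_id") == subject_id
  sort(unique(run_field(h, "modality_label")[keep]))
}

#' All modality labels in a hierarchy
#' @param h an `mrc_hierarchy`.
#' @return Sorted character vector.
#' @export
modalities <- function(h) sort(unique(unname(run_field(h, "modality_label"))))

#' All subject identifiers in a hierarchy
#' @param h an `mrc_hierarchy`.
#' @param modality_label optional: restrict to one modality.
#' @return Sorted character vector.
#' @export
subjects <- function(h, modality_label = NULL) {
  keep <- rep(TRUE, length(h$runs))
  if (!is.null(modality_label))
    keep <- run_field(h, "modality_label") == modality_label
  sort(unique(unname(run_field(h, "subject_id")[keep])))
}

#' Modality-first index: modality -> subject -> session -> run ids
#'
#' Derived deterministically from the run set (keys sorted), so two
#' hierarchies holding the same runs index identically whatever the
#' insertion order.
#'
#' @param h an `mrc_hierarchy`.
#' @return Nested named list of run-id character vectors.
#' @export
index_by_modality <- function(h) {
  out <- list()
  for (m in modalities(h)) {
    out[[m]] <- list()
    rs <- runs_for(h, m)
    for (r in rs) {
      out[[m]][[r$subject_id]][[r$session_id]] <-
        c(out[[m]][[r$subject_id]][[r$session_id]], r$run_id)
    }
  }
  out
}

#' Subject-first index: subject -> modality -> run ids
#' @param h an `mrc_hierarchy`.
#' @return Nested named list of run-id character vectors.
#' @export
index_by_subject <- function(h) {
  out <- list()
  for (s in subjects(h)) {
    out[[s]] <- list()
    for (m in modalities_for(h, s)) {
      rs <- Filter(function(r) r$subject_id == s, runs_for(h, m))
      out[[s]][[m]] <- vapply(rs, `[[`, "", "run_id")
    }
  }
  out
}

#' @export
print.mrc_hierarchy <- function(x, ...) {
  cat(sprintf("<mrc_hierarchy '%s' (%s): %d runs, %d subjects, %d modalities>\n",
              x$dataset_name, x$format, length(x$runs),
              length(subjects(x)), length(modalities(x))))
  invisible(x)
}

#' Serialize a hierarchy to JSON (debugging aid)
#' @param h an `mrc_hierarchy`.
#' @param path optional file to write.
#' @return JSON string, invisibly if written to file.
#' @export
hierarchy_to_json <- function(h, path = NULL) {
  runs <- lapply(runs_for_all(h), function(r) {
    list(run_id = r$run_id, subject_id = r$subject_id,
         session_id = r$session_id, modality_label = r$modality_label,
         vendor = r$vendor, echo_number = r$echo_number,
         entities = r$entities,
         parameters = lapply(r$parameters, param_to_list))
  })
  js <- jsonlite::toJSON(list(dataset_name = h$dataset_name,
                              format = h$format, runs = runs),
                         auto_unbox = TRUE, digits = I(17), null = "null",
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# all runs in deterministic (subject, session, run_id) order
runs_for_all <- function(h) {
  rs <- h$runs
  if (!length(rs)) return(list())
  ord <- order(vapply(rs, `[[`, "", "subject_id"),
               vapply(rs, `[[`, "", "session_id"),
               vapply(rs, `[[`, "", "run_id"))
  unname(rs[ord])
}
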