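# Incremental monitoring over a growing DICOM archive. The state file
# fingerprints every file seen so far and caches the parsed per-file
# metadata record; an incremental audit re-reads only new or changed files,
# then rebuilds the hierarchy from the cache so the result is always
# identical to a from-scratch audit of the current tree (deleted files
# simply drop out). The cache accelerates header reads; it never owns the
# truth.

#' Empty monitor state
#' @return A list of class `mrc_monitor_state`.
#' @export
empty_state <- function() {
  structure(list(files = list(), records = list(), last_audit = NULL),
            class = "mrc_monitor_state")
}

#' Detect new or changed files under a root
#'
#' A file counts as new when its path is absent from the state, or changed
#' when its size or content fingerprint (md5) differs.
#'
#' @param root directory to scan.
#' @param state monitor state from a previous run, or [empty_state()].
#' @return list with `new_files` (relative paths), `deleted_files`, and
#'   `state` with an updated fingerprint table.
#' @export
detect_new <- function(root, state = empty_state()) {
  if (!dir.exists(root)) stop("root directory not found: ", root)
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  files <- files[!dir.exists(file.path(root, files))]
  new_files <- character()
  tab <- list()
  for (f in sort(files)) {
    abs <- file.path(root, f)
    info <- file.info(abs)
    md5 <- unname(tools::md5sum(abs))
    prev <- state$files[[f]]
    if (is.null(prev) || !identical(prev$md5, md5)) new_files <- c(new_files, f)
    tab[[f]] <- list(size = unname(info$size),
                     mtime = as.character(info$mtime), md5 = md5)
  }
  deleted <- setdiff(names(state$files), files)
  state$files <- tab
  list(new_files = new_files, deleted_files = deleted, state = state)
}

serialize_record <- function(rec) {
  rec$params <- lapply(rec$params, param_to_list)
  rec
}
deserialize_record <- function(rec) {
  rec$params <- lapply(rec$params, param_from_list)
  rec$echo_number <- suppressWarnings(as.integer(rec$echo_number))
  if (!length(rec$echo_number)) rec$echo_number <- NA_integer_
  if (is.null(rec$acquisition_time)) rec$acquisition_time <- NA_character_
  if (is.null(rec$study_uid)) rec$study_uid <- NA_character_
  rec
}

#' Save / load monitor state
#'
#' State is one inspectable JSON file. An unreadable or corrupt state file
#' degrades to a first run with a warning rather than failing.
#'
#' @param state an `mrc_monitor_state`.
#' @param path state file path.
#' @return `load_state` returns an `mrc_monitor_state`.
#' @export
save_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = I(17), na = "null",
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  if (!file.exists(path)) return(empty_state())
  st <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) NULL)
  if (is.null(st) || !is.list(st)) {
    warning("unreadable state file '", path, "'; treating as first run")
    return(empty_state())
  }
  out <- empty_state()
  out$files <- st$files
  out$records <- st$records
  out$last_audit <- st$last_audit
  out
}

#' Incremental audit of a DICOM tree
#'
#' Reads only files added or changed since `state` was taken, drops cache
#' entries for deleted files, rebuilds the hierarchy and audits it. The
#' report equals a from-scratch [scan_dicom_tree()] + [audit_dataset()] of
#' the current tree.
#'
#' @param root DICOM tree root.
#' @param state previous [empty_state()] / returned state.
#' @param tol tolerance.
#' @param strata_keys see [stratify()].
#' @param params parameter roster.
#' @param dataset_name dataset label for the report.
#' @param timestamp injectable report timestamp.
#' @return list with `report` (`mrc_report`), `hierarchy`, and the updated
#'   `state`.
#' @export
incremental_audit <- function(root, state = empty_state(),
                              tol = tolerance_spec(0),
                              strata_keys = character(),
                              params = default_audit_params(),
                              dataset_name = basename(normalizePath(root)),
                              timestamp = NULL) {
  if (!inherits(tol, "mrc_tolerance")) tol <- tolerance_spec(tol)
  det <- detect_new(root, state)
  state <- det$state
  for (f in det$new_files) {
    abs <- file.path(root, f)
    if (!is_dicom_file(abs)) {
      state$records[[f]] <- list(nondicom = TRUE)
      next
    }
    rec <- tryCatch(read_dicom_record(abs), error = function(e) {
      warning("skipping unreadable DICOM file ", abs)
      NULL
    })
    state$records[[f]] <- if (is.null(rec)) list(nondicom = TRUE)
                          else serialize_record(rec)
  }
  for (f in det$deleted_files) state$records[[f]] <- NULL
  recs <- Filter(function(r) !isTRUE(r$nondicom),
                 state$records[names(state$records) %in% names(state$files)])
  if (!length(recs))
    stop("no readable DICOM files under ", root, " (empty dataset)")
  h <- records_to_hierarchy(lapply(unname(recs), deserialize_record),
                            dataset_name)
  summaries <- audit_dataset(h, tol = tol, strata_keys = strata_keys,
                             params = params)
  report <- compliance_report(summaries, dataset_name,
                              tolerance = tol$global_t, timestamp = timestamp)
  state$last_audit <- report$timestamp
  list(report = report, hierarchy = h, state = state)
}
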