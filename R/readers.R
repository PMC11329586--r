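# Dataset readers. Both readers populate the same hierarchy type so the
# audit engine never cares where metadata came from. Neither reader trusts
# directory layout: DICOM files are grouped by SeriesInstanceUID wherever
# they sit on disk, and BIDS runs are keyed by their entity-bearing
# filenames.

normalize_vendor <- function(x) {
  if (is.null(x) || !length(x)) return("")
  x <- as.character(x)[1]
  if (is.na(x) || !nzchar(trimws(x))) return("")
  toupper(strsplit(trimws(x), "[ /]+")[[1]][1])
}

# Per-file extraction shared by the batch scanner and the incremental
# monitor: one flat record per DICOM file, cheap to cache as JSON.
read_dicom_record <- function(path) {
  ds <- dicom_read(path)
  vendor <- normalize_vendor(dcm_string(ds, "0008,0070"))
  protocol <- dcm_string(ds, "0018,1030")
  if (is.na(protocol) || !nzchar(protocol)) protocol <- dcm_string(ds, "0008,103E")
  series_uid <- dcm_string(ds, "0020,000E")
  if (is.na(series_uid)) stop("no SeriesInstanceUID in ", path)
  inst <- dcm_numeric(ds, "0020,0013")

  voc <- param_vocabulary()
  params <- list()
  for (i in seq_len(nrow(voc))) {
    nm <- voc$name[i]
    if (is.na(voc$tag_group[i])) next   # private-header-only parameters
    key <- sprintf("%s,%s", voc$tag_group[i], voc$tag_element[i])
    if (voc$kind[i] == "numeric") {
      val <- dcm_numeric(ds, key)
      val <- if (length(val)) val[1] else NULL
      # GE reports field of view in cm where Siemens/Philips use mm
      if (!is.null(val) && nm == "FieldOfView" && vendor == "GE") val <- val * 10
    } else if (voc$kind[i] == "multivalued") {
      val <- dcm_numeric(ds, key)
      if (!length(val)) val <- NULL
    } else {
      val <- dcm_string(ds, key)
      if (is.na(val) || !nzchar(val)) val <- NULL
    }
    params[[nm]] <- param_value(nm, val, source = "standard-tag",
                                present = !is.null(val))
  }
  # Siemens private header; GE/Philips private headers are skipped.
  priv <- list()
  if (vendor == "SIEMENS" && !is.null(ds[["0029,1020"]]))
    priv <- parse_siemens_private(ds[["0029,1020"]]$bytes)
  for (nm in c("ShimMode", "ParallelImaging", "MultiSliceMode")) {
    params[[nm]] <- if (!is.null(priv[[nm]])) priv[[nm]]
                    else param_value(nm, NULL, source = "private-header",
                                     present = FALSE)
  }

  list(path = path,
       series_uid = series_uid,
       study_uid = dcm_string(ds, "0020,000D"),
       patient_id = dcm_string(ds, "0010,0020"),
       instance_number = if (length(inst)) inst[1] else Inf,
       protocol_name = if (is.na(protocol)) "" else protocol,
       vendor = vendor,
       echo_number = {
         e <- dcm_numeric(ds, "0018,0086")
         if (length(e)) as.integer(e[1]) else NA_integer_
       },
       acquisition_time = {
         d <- dcm_string(ds, "0008,0022"); t <- dcm_string(ds, "0008,0032")
         if (!is.na(d)) paste0(d, if (!is.na(t)) t else "") else NA_character_
       },
       params = params)
}

# Collapse per-file records into one run per series, using the instance
# with the lowest InstanceNumber as the series representative (per-series
# acquisition parameters are constant in well-formed data).
records_to_hierarchy <- function(records, dataset_name) {
  h <- new_hierarchy(dataset_name, "dicom")
  by_series <- split(records, vapply(records, `[[`, "", "series_uid"))
  for (uid in sort(names(by_series))) {
    grp <- by_series[[uid]]
    rep <- grp[[which.min(vapply(grp, `[[`, 0, "instance_number"))]]
    params <- lapply(rep$params, function(p) {
      if (inherits(p, "mrc_param")) p else param_from_list(p)
    })
    h <- add_run(h, new_run(
      run_id = uid,
      subject_id = rep$patient_id,
      session_id = if (is.na(rep$study_uid)) "" else rep$study_uid,
      modality_label = normalize_label(rep$protocol_name),
      vendor = rep$vendor,
      parameters = params,
      echo_number = rep$echo_number,
      acquisition_time = rep$acquisition_time))
  }
  h
}

#' Scan a DICOM tree into a dataset hierarchy
#'
#' Walks every file under `root` regardless of layout, keeps those with a
#' valid Part-10 preamble, and builds one run per distinct
#' SeriesInstanceUID from the lowest-numbered instance of each series.
#' Unreadable files are skipped with a warning, never aborting the scan.
#'
#' @param root directory to scan.
#' @param dataset_name name recorded in reports; defaults to the directory
#'   name.
#' @return An `mrc_hierarchy` with attributes `n_skipped_nondicom` and
#'   `n_corrupt`.
#' @export
scan_dicom_tree <- function(root, dataset_name = basename(normalizePath(root))) {
  if (!dir.exists(root)) stop("root directory not found: ", root)
  files <- list.files(root, recursive = TRUE, full.names = TRUE, all.files = FALSE)
  files <- files[!dir.exists(files)]
  is_dcm <- vapply(files, is_dicom_file, FALSE)
  n_skipped <- sum(!is_dcm)
  records <- list()
  n_corrupt <- 0L
  for (f in files[is_dcm]) {
    rec <- tryCatch(read_dicom_record(f), error = function(e) {
      warning("skipping unreadable DICOM file ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) n_corrupt <- n_corrupt + 1L else records[[length(records) + 1L]] <- rec
  }
  if (!length(records))
    stop("no readable DICOM files under ", root, " (empty dataset)")
  h <- records_to_hierarchy(records, dataset_name)
  attr(h, "n_skipped_nondicom") <- n_skipped
  attr(h, "n_corrupt") <- n_corrupt
  h
}

bids_entities <- function(filename) {
  base <- sub("\\.nii(\\.gz)?$", "", basename(filename))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  suffix <- parts[length(parts)]
  kv <- parts[-length(parts)]
  kv <- kv[grepl("-", kv, fixed = TRUE)]
  keys <- sub("-.*$", "", kv)
  vals <- sub("^[^-]*-", "", kv)
  names(vals) <- keys
  list(suffix = suffix, entities = vals)
}

#' Read a BIDS dataset into a hierarchy
#'
#' One run per imaging file (`.nii`/`.nii.gz`); acquisition parameters come
#' from the matching JSON sidecar (BIDS stores seconds for TR/TE; converted
#' to ms at read time). The modality label combines datatype, differentiating
#' entities (task, acq, dir, ...) and suffix so that e.g. task-rest and
#' task-nback BOLD runs audit separately. A missing sidecar yields a run
#' with every parameter marked absent and a `"missing-sidecar"` flag; an
#' unparseable sidecar skips the run with a warning.
#'
#' @param root BIDS dataset root.
#' @param dataset_name name recorded in reports.
#' @return An `mrc_hierarchy` (format `"bids"`).
#' @export
read_bids_tree <- function(root, dataset_name = basename(normalizePath(root))) {
  if (!dir.exists(root)) stop("root directory not found: ", root)
  root <- normalizePath(root)
  imgs <- list.files(root, pattern = "\\.nii(\\.gz)?$", recursive = TRUE,
                     full.names = TRUE)
  imgs <- imgs[grepl("(^|/)sub-[^/]+/", substring(imgs, nchar(root) + 2L))]
  if (!length(imgs)) stop("no BIDS imaging files under ", root, " (empty dataset)")
  h <- new_hierarchy(dataset_name, "bids")
  voc <- param_vocabulary()
  for (img in sort(imgs)) {
    rel <- substring(img, nchar(root) + 2L)
    ent <- bids_entities(img)
    e <- ent$entities
    if (is.null(e["sub"]) || is.na(e["sub"])) next
    datatype <- basename(dirname(img))
    diff_keys <- setdiff(names(e), c("sub", "ses", "run", "echo"))
    ent_str <- if (length(diff_keys))
      paste(paste0(diff_keys, "-", e[diff_keys]), collapse = "_") else ""
    label <- normalize_label(paste(datatype, ent_str, ent$suffix))

    sidecar <- sub("\\.nii(\\.gz)?$", ".json", img)
    flags <- character()
    meta <- NULL
    if (!file.exists(sidecar)) {
      flags <- "missing-sidecar"
    } else {
      meta <- tryCatch(jsonlite::fromJSON(sidecar, simplifyVector = TRUE),
                       error = function(er) NULL)
      if (is.null(meta)) {
        warning("skipping run with unparseable sidecar: ", sidecar)
        next
      }
    }
    params <- list()
    for (i in seq_len(nrow(voc))) {
      nm <- voc$name[i]; key <- voc$sidecar_key[i]
      if (is.na(key)) next
      val <- if (!is.null(meta)) meta[[key]] else NULL
      if (!is.null(val) && voc$kind[i] == "numeric") {
        val <- as.numeric(val)[1] * voc$sidecar_scale[i]
      } else if (!is.null(val) && voc$kind[i] == "multivalued") {
        val <- as.numeric(unlist(val))
      } else if (!is.null(val)) {
        val <- as.character(val)[1]
      }
      params[[nm]] <- param_value(nm, val, source = "sidecar",
                                  present = !is.null(val))
    }
    h <- add_run(h, new_run(
      run_id = rel,
      subject_id = paste0("sub-", e[["sub"]]),
      session_id = if (!is.na(e["ses"])) paste0("ses-", e[["ses"]]) else "ses-1",
      modality_label = label,
      vendor = normalize_vendor(if (!is.null(meta)) meta[["Manufacturer"]] else ""),
      parameters = params,
      echo_number = if (!is.na(e["echo"])) as.integer(e[["echo"]]) else NA_integer_,
      entities = ent_str,
      flags = flags))
  }
  if (!length(h$runs)) stop("no readable BIDS runs under ", root)
  h
}
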