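# Synthetic dataset generator: emits standards-valid (tiny) DICOM trees
# and/or BIDS trees from a known base protocol with controlled deviation
# injection, plus a ground-truth manifest. Every audit stage is testable
# against the manifest without external data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Describe one synthetic modality
#'
#' @param name protocol name written to DICOM ProtocolName; normalizes to
#'   the audit's modality label.
#' @param datatype BIDS datatype directory (`anat`, `func`, `fmap`, `dwi`).
#' @param suffix BIDS filename suffix (`T1w`, `bold`, `epi`, `dwi`).
#' @param entities BIDS differentiating entity string (e.g. `"task-rest"`).
#' @param params named list of base parameter values (vocabulary names;
#'   package units: ms, degrees, Hz/pixel, T, mm).
#' @return A list of class `mrc_modality_spec`.
#' @export
modality_spec <- function(name, datatype, suffix, entities = "", params) {
  structure(list(name = name, datatype = datatype, suffix = suffix,
                 entities = entities, params = params),
            class = "mrc_modality_spec")
}

#' Default synthetic modalities
#'
#' A small but representative session: a 3T MPRAGE-like T1w, a task-rest
#' BOLD EPI and its matching fieldmap (identical geometry, as a correct
#' acquisition requires). Values are typical vendor-console numbers for a
#' 3T research protocol.
#'
#' @return List of [modality_spec()].
#' @export
default_modalities <- function() {
  ang <- c(1, 0, 0, 0, 1, 0)
  list(
    modality_spec("anat_T1w", "anat", "T1w", "", list(
      RepetitionTime = 2300, EchoTime = 2.98, FlipAngle = 9,
      PhaseEncodingDirection = "PA", PixelBandwidth = 240,
      EchoTrainLength = 16, PhaseEncodingSteps = 255,
      MagneticFieldStrength = 3, SequenceVariant = "SK_SP",
      ShimMode = "tune_up", ParallelImaging = "GRAPPA",
      MultiSliceMode = "sequential", FieldOfView = 256,
      NumberOfSlices = 176, SliceThickness = 1, Angulation = ang)),
    modality_spec("func_task-rest_bold", "func", "bold", "task-rest", list(
      RepetitionTime = 800, EchoTime = 30, FlipAngle = 52,
      PhaseEncodingDirection = "AP", PixelBandwidth = 2290,
      EchoTrainLength = 52, PhaseEncodingSteps = 90,
      MagneticFieldStrength = 3, SequenceVariant = "SK_SS",
      ShimMode = "tune_up", ParallelImaging = "GRAPPA",
      MultiSliceMode = "interleaved", FieldOfView = 216,
      NumberOfSlices = 60, SliceThickness = 2.4, Angulation = ang)),
    modality_spec("fmap_dir-AP_epi", "fmap", "epi", "dir-AP", list(
      RepetitionTime = 8000, EchoTime = 66, FlipAngle = 90,
      PhaseEncodingDirection = "AP", PixelBandwidth = 2290,
      EchoTrainLength = 52, PhaseEncodingSteps = 90,
      MagneticFieldStrength = 3, SequenceVariant = "SK_SS",
      ShimMode = "tune_up", ParallelImaging = "GRAPPA",
      MultiSliceMode = "interleaved", FieldOfView = 216,
      NumberOfSlices = 60, SliceThickness = 2.4, Angulation = ang)))
}

#' Describe one injected deviation
#'
#' @param parameter vocabulary name to perturb.
#' @param mode `"numeric-shift"` (apply `factor` and/or add `delta`),
#'   `"categorical-flip"` (replace with `alternate`), or `"drop-field"`
#'   (remove the parameter from the emitted metadata).
#' @param p fraction of subjects to affect, in `[0, 1]`; the affected set
#'   is the first `floor(p * n)` subjects of a seeded shuffle, so the
#'   manifest records it exactly.
#' @param delta,factor,alternate mode-specific payload.
#' @param modalities restrict to these modality `name`s (default: every
#'   modality carrying the parameter).
#' @return A list of class `mrc_deviation_spec`.
#' @export
deviation_spec <- function(parameter,
                           mode = c("numeric-shift", "categorical-flip", "drop-field"),
                           p, delta = 0, factor = 1, alternate = NULL,
                           modalities = NULL) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop("deviation fraction p must lie in [0, 1]")
  if (mode == "categorical-flip" && is.null(alternate))
    stop("categorical-flip needs an alternate token")
  structure(list(parameter = parameter, mode = mode, p = p, delta = delta,
                 factor = factor, alternate = alternate,
                 modalities = modalities),
            class = "mrc_deviation_spec")
}

#' Configure a synthetic fixture
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_subject sessions per subject.
#' @param modalities list of [modality_spec()].
#' @param vendor_mix named proportions over manufacturer tokens; subjects
#'   are assigned a vendor by a seeded draw.
#' @param deviations list of [deviation_spec()].
#' @param seed integer; fixes the generator completely (two runs with the
#'   same config produce byte-identical manifests).
#' @return A list of class `mrc_fixture_config`.
#' @export
fixture_config <- function(n_subjects = 20L, sessions_per_subject = 1L,
                           modalities = default_modalities(),
                           vendor_mix = c(SIEMENS = 0.6, GE = 0.25, PHILIPS = 0.15),
                           deviations = list(), seed = 42L) {
  stopifnot(n_subjects >= 1L, sessions_per_subject >= 1L,
            abs(sum(vendor_mix) - 1) < 1e-9)
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 modalities = modalities, vendor_mix = vendor_mix,
                 deviations = deviations, seed = as.integer(seed)),
            class = "mrc_fixture_config")
}

# Ground truth: per-run parameter maps after injection, plus the exact
# non-compliant subject set per modality. All randomness is consumed in a
# fixed order under the config seed.
build_truth <- function(config) {
  n <- config$n_subjects
  subj_ids <- sprintf("sub-%03d", seq_len(n))
  with_seed(config$seed, {
    vendors <- sample(names(config$vendor_mix), n, replace = TRUE,
                      prob = config$vendor_mix)
    targets <- lapply(config$deviations, function(d) {
      shuffled <- sample(n)
      shuffled[seq_len(floor(d$p * n))]
    })
  })
  runs <- list()
  noncompliant <- list()
  for (s in seq_len(n)) {
    for (e in seq_len(config$sessions_per_subject)) {
      for (mi in seq_along(config$modalities)) {
        mspec <- config$modalities[[mi]]
        params <- mspec$params
        dropped <- character()
        applied <- character()
        for (di in seq_along(config$deviations)) {
          d <- config$deviations[[di]]
          if (!(s %in% targets[[di]])) next
          if (!is.null(d$modalities) && !(mspec$name %in% d$modalities)) next
          if (is.null(params[[d$parameter]])) next
          if (d$mode == "numeric-shift") {
            params[[d$parameter]] <- params[[d$parameter]] * d$factor + d$delta
          } else if (d$mode == "categorical-flip") {
            params[[d$parameter]] <- d$alternate
          } else {
            params[d$parameter] <- list(NULL)
            dropped <- c(dropped, d$parameter)
          }
          applied <- c(applied, paste0(d$parameter, ":", d$mode))
        }
        params <- params[!vapply(params, is.null, FALSE)]
        label <- normalize_label(mspec$name)
        if (length(applied)) {
          noncompliant[[label]] <- sort(unique(c(noncompliant[[label]], subj_ids[s])))
        }
        runs[[length(runs) + 1L]] <- list(
          subject = subj_ids[s],
          session = sprintf("ses-%02d", e),
          modality = mspec$name,
          modality_label = label,
          datatype = mspec$datatype, suffix = mspec$suffix,
          entities = mspec$entities,
          vendor = vendors[s],
          subject_index = s, session_index = e, modality_index = mi,
          params = params, dropped = dropped, deviations = applied)
      }
    }
  }
  list(seed = config$seed, n_subjects = n,
       sessions_per_subject = config$sessions_per_subject,
       vendors = stats::setNames(vendors, subj_ids),
       runs = runs,
       noncompliant_subjects = if (length(noncompliant))
         noncompliant[sort(names(noncompliant), method = "radix")]
       else stats::setNames(list(), character()))
}

series_uid <- function(seed, s, e, mi) sprintf("1.2.826.0.1.99999.%d.%d.%d.%d", seed, s, e, mi)
study_uid <- function(seed, s, e) sprintf("1.2.826.0.1.99999.%d.%d.%d", seed, s, e)

write_dicom_run <- function(run, seed, dir, instances = 1L) {
  voc <- param_vocabulary()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suid <- series_uid(seed, run$subject_index, run$session_index, run$modality_index)
  for (inst in seq_len(instances)) {
    els <- list(
      dcm_element(0x0008L, 0x0016L, "UI", "1.2.840.10008.5.1.4.1.1.4"),
      dcm_element(0x0008L, 0x0018L, "UI", paste0(suid, ".", inst)),
      dcm_element(0x0008L, 0x0022L, "DA", "20240115"),
      dcm_element(0x0008L, 0x0032L, "TM",
                  sprintf("%02d%02d%02d", run$session_index,
                          run$modality_index, inst)),
      dcm_element(0x0008L, 0x0060L, "CS", "MR"),
      dcm_element(0x0008L, 0x0070L, "LO", run$vendor),
      dcm_element(0x0008L, 0x103EL, "LO", run$modality),
      dcm_element(0x0010L, 0x0020L, "LO", run$subject),
      dcm_element(0x0018L, 0x1030L, "LO", run$modality),
      dcm_element(0x0020L, 0x000DL, "UI",
                  study_uid(seed, run$subject_index, run$session_index)),
      dcm_element(0x0020L, 0x000EL, "UI", suid),
      dcm_element(0x0020L, 0x0013L, "IS", inst),
      dcm_element(0x0028L, 0x0010L, "US", 2L),
      dcm_element(0x0028L, 0x0011L, "US", 2L),
      dcm_element(0x0028L, 0x0100L, "US", 8L),
      dcm_element(0x7FE0L, 0x0010L, "OB", as.raw(c(0, 64, 128, 255)))
    )
    for (i in seq_len(nrow(voc))) {
      nm <- voc$name[i]
      if (is.na(voc$tag_group[i])) next
      val <- run$params[[nm]]
      if (is.null(val)) next
      if (nm == "FieldOfView" && run$vendor == "GE") val <- val / 10  # GE uses cm
      els[[length(els) + 1L]] <- dcm_element(
        strtoi(voc$tag_group[i], 16L), strtoi(voc$tag_element[i], 16L),
        voc$vr[i], val)
    }
    if (run$vendor == "SIEMENS") {
      blk <- ascconv_block(shim_mode = run$params$ShimMode,
                           parallel_imaging = run$params$ParallelImaging,
                           multi_slice_mode = run$params$MultiSliceMode)
      els <- c(els, list(
        dcm_element(0x0029L, 0x0010L, "LO", "SIEMENS CSA HEADER"),
        dcm_element(0x0029L, 0x1020L, "OB", charToRaw(blk))))
    }
    dicom_write(file.path(dir, sprintf("i%03d.dcm", inst)), els,
                paste0(suid, ".", inst))
  }
}

anat_to_bids_ped <- c(AP = "j-", PA = "j", RL = "i", LR = "i-", IS = "k", SI = "k-")

write_bids_run <- function(run, root) {
  voc <- param_vocabulary()
  dir <- file.path(root, run$subject, run$session, run$datatype)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- paste0(run$subject, "_", run$session,
                 if (nzchar(run$entities)) paste0("_", run$entities) else "",
                 "_", run$suffix)
  writeLines("MRC synthetic imaging stub (no pixel data)", file.path(dir, paste0(stem, ".nii")))
  meta <- list(Manufacturer = run$vendor)
  for (i in seq_len(nrow(voc))) {
    nm <- voc$name[i]; key <- voc$sidecar_key[i]
    if (is.na(key)) next
    val <- run$params[[nm]]
    if (is.null(val)) next
    if (voc$kind[i] == "numeric") val <- val / voc$sidecar_scale[i]
    if (nm == "PhaseEncodingDirection" && val %in% names(anat_to_bids_ped))
      val <- unname(anat_to_bids_ped[[val]])
    meta[[key]] <- val
  }
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

#' Generate a synthetic dataset on disk
#'
#' Emits the configured acquisitions as a DICOM tree (valid Part-10 files
#' with a token 2x2 pixel payload; Siemens runs carry an ASCCONV private
#' block), a BIDS tree (stub imaging files + JSON sidecars, TR/TE in
#' seconds, axis-token PED), or both, plus `manifest.json` recording the
#' exact post-injection truth.
#'
#' @param config a [fixture_config()].
#' @param out_dir output directory; must be empty unless `force`.
#' @param format `"dicom"`, `"bids"` or `"both"`.
#' @param force overwrite a non-empty `out_dir`.
#' @return The manifest list (also written to `out_dir/manifest.json`).
#' @export
generate_fixture <- function(config, out_dir,
                             format = c("dicom", "bids", "both"),
                             force = FALSE) {
  stopifnot(inherits(config, "mrc_fixture_config"))
  format <- match.arg(format)
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE,
                                               no.. = TRUE)) && !force)
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- build_truth(config)
  if (format %in% c("dicom", "both")) {
    for (run in truth$runs) {
      write_dicom_run(run, config$seed,
                      file.path(out_dir, "dicom", run$subject, run$session,
                                gsub("[^A-Za-z0-9_-]", "_", run$modality)))
    }
  }
  if (format %in% c("bids", "both")) {
    broot <- file.path(out_dir, "bids")
    dir.create(broot, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(Name = "mrc synthetic fixture",
                              BIDSVersion = "1.8.0"),
                         file.path(broot, "dataset_description.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    for (run in truth$runs) write_bids_run(run, broot)
  }
  manifest <- c(truth, list(format = format))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Generate the same acquisitions as both DICOM and BIDS
#'
#' Convenience wrapper around [generate_fixture()] with `format = "both"`,
#' for reader-equivalence testing (same truth, two serializations, units
#' converted per format).
#'
#' @inheritParams generate_fixture
#' @return The manifest list.
#' @export
generate_paired <- function(config, out_dir, force = FALSE) {
  generate_fixture(config, out_dir, format = "both", force = force)
}
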