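# In-memory and on-disk fixture builders shared across the suite. All
# randomness is seeded by the caller; nothing here touches the network or
# data outside tempdir().

base_values <- function() {
  list(RepetitionTime = 2300, EchoTime = 3, FlipAngle = 9,
       PhaseEncodingDirection = "AP", PixelBandwidth = 240,
       EchoTrainLength = 16, PhaseEncodingSteps = 255,
       MagneticFieldStrength = 3, SequenceVariant = "SK_SP",
       ShimMode = "tune_up", ParallelImaging = "GRAPPA")
}

make_run <- function(subject, modality = "ANAT_T1W", values = base_values(),
                     session = "ses-01", vendor = "SIEMENS",
                     run_id = NULL, echo = NA_integer_, entities = "",
                     absent = character()) {
  values <- values[setdiff(names(values), absent)]
  if (is.null(run_id)) run_id <- paste(subject, session, modality, sep = ":")
  new_run(run_id, subject, session, modality, vendor = vendor,
          parameters = params_from_values_pub(values, absent = absent),
          echo_number = echo, entities = entities)
}

# public wrapper over the internal constructor so helpers stay on the
# exported surface where possible
params_from_values_pub <- function(values, absent = character()) {
  out <- lapply(names(values), function(nm) param_value(nm, values[[nm]]))
  names(out) <- names(values)
  for (nm in absent)
    out[[nm]] <- param_value(nm, NULL, present = FALSE)
  out
}

make_hier <- function(runs, name = "test", format = "dicom") {
  h <- new_hierarchy(name, format)
  for (r in runs) h <- add_run(h, r)
  h
}

# a cohort of n subjects on one modality, with chosen subjects deviant in
# one parameter
cohort_hier <- function(n, deviants = character(), parameter = "EchoTime",
                        deviant_value = 3.5, modality = "ANAT_T1W") {
  runs <- lapply(sprintf("sub-%03d", seq_len(n)), function(s) {
    v <- base_values()
    if (s %in% deviants) v[[parameter]] <- deviant_value
    make_run(s, modality, v)
  })
  make_hier(runs)
}

siemens_config <- function(n_subjects, deviations = list(), seed = 1L,
                           sessions = 1L) {
  fixture_config(n_subjects = n_subjects, sessions_per_subject = sessions,
                 vendor_mix = c(SIEMENS = 1), deviations = deviations,
                 seed = seed)
}

mixed_deviations <- function() {
  list(
    deviation_spec("EchoTime", "numeric-shift", p = 0.15, factor = 1.10,
                   modalities = "anat_T1w"),
    deviation_spec("PhaseEncodingDirection", "categorical-flip", p = 0.10,
                   alternate = "PA", modalities = "func_task-rest_bold"),
    deviation_spec("PhaseEncodingDirection", "drop-field", p = 0.10,
                   modalities = "fmap_dir-AP_epi"))
}

runs_for_all_pub <- function(h) {
  unlist(lapply(modalities(h), function(m) runs_for(h, m)), recursive = FALSE)
}

# set of (subject, modality) pairs flagged non-compliant by an audit
audit_noncompliant_set <- function(summaries) {
  out <- character()
  for (s in summaries) {
    nc <- names(s$subject_status)[s$subject_status == "non-compliant"]
    if (length(nc)) out <- c(out, paste(s$modality_label, nc, sep = "/"))
  }
  sort(out)
}

manifest_noncompliant_set <- function(manifest) {
  out <- character()
  for (m in names(manifest$noncompliant_subjects))
    out <- c(out, paste(m, unlist(manifest$noncompliant_subjects[[m]]), sep = "/"))
  sort(out)
}
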