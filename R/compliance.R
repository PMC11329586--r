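#' Tolerance specification for numeric comparisons
#'
#' A global tolerance fraction `t` with optional per-parameter overrides.
#' Numeric observed values are accepted inside `R +/- t*R` (closed
#' interval); categorical and multivalued parameters ignore `t` entirely
#' and must match exactly.
#'
#' @param global_t fraction in `[0, 1]`; `0` means absolute equivalence
#'   (up to a 1e-6 epsilon absorbing float-serialization noise).
#' @param overrides named numeric vector of per-parameter fractions.
#' @return An object of class `mrc_tolerance`.
#' @export
tolerance_spec <- function(global_t = 0, overrides = numeric()) {
  stopifnot(is.numeric(global_t), length(global_t) == 1L)
  if (global_t < 0 || global_t > 1) stop("tolerance must lie in [0, 1]")
  if (length(overrides) && (any(overrides < 0) || any(overrides > 1)))
    stop("tolerance overrides must lie in [0, 1]")
  structure(list(global_t = global_t, overrides = overrides),
            class = "mrc_tolerance")
}

tol_for <- function(tol, name) {
  if (!inherits(tol, "mrc_tolerance")) tol <- tolerance_spec(tol)
  if (name %in% names(tol$overrides)) unname(tol$overrides[[name]]) else tol$global_t
}

#' Acceptable range around a numeric reference value
#'
#' The closed interval `R +/- t*R`. Both bounds are inclusive; display
#' rounding happens only in reports.
#'
#' @param R finite numeric reference value.
#' @param t tolerance fraction in `[0, 1]`.
#' @return Numeric vector `c(lo, hi)`.
#' @export
acceptable_range <- function(R, t) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("tolerance must be a non-negative number")
  if (t > 1) stop("tolerance must lie in [0, 1]")
  c(R - t * R, R + t * R)
}

# epsilon for t = 0 numeric equality, in the parameter's native unit:
# absolute equivalence cannot mean bit equality across formats (DICOM DS
# strings vs JSON doubles).
.mrc_eps <- 1e-6

#' Is an observed parameter value compliant with the reference?
#'
#' Numeric: inside the closed interval `R +/- t*R` (with `t = 0`, within a
#' 1e-6 epsilon of `R`). Categorical and multivalued: exact token/tuple
#' equality regardless of `t`. Comparing parameters of different kinds is a
#' vocabulary violation and errors.
#'
#' @param observed,reference [param_value()] objects of the same name and
#'   kind, both present.
#' @param t tolerance fraction.
#' @return logical scalar.
#' @export
value_compliant <- function(observed, reference, t = 0) {
  stopifnot(inherits(observed, "mrc_param"), inherits(reference, "mrc_param"))
  if (observed$kind != reference$kind)
    stop("kind mismatch for '", observed$name, "': ",
         observed$kind, " vs ", reference$kind)
  if (!observed$present || !reference$present)
    stop("value_compliant requires both values present")
  if (observed$kind == "numeric") {
    R <- reference$value; obs <- observed$value
    if (t <= 0) return(abs(obs - R) <= .mrc_eps)
    rng <- acceptable_range(R, t)
    slack <- 1e-9 * max(1, abs(R))
    return(obs >= rng[1] - slack && obs <= rng[2] + slack)
  }
  if (observed$kind == "categorical")
    return(identical(trimws(observed$value), trimws(reference$value)))
  # multivalued: ordered tuple equality (numeric entries up to epsilon)
  a <- observed$value; b <- reference$value
  if (length(a) != length(b)) return(FALSE)
  if (is.numeric(a) && is.numeric(b)) return(all(abs(a - b) <= .mrc_eps))
  all(as.character(a) == as.character(b))
}

#' Infer a reference protocol by majority vote
#'
#' For each requested parameter, the modal value over the runs where it is
#' present (absent values never vote). Ties break deterministically: the
#' smallest numeric value, or the lexicographically smallest token — so
#' inference is independent of run order. Parameters absent from every run
#' are omitted and listed in the `uninferable` attribute.
#'
#' @param runs list of runs (same modality).
#' @param names parameters to infer; defaults to [default_audit_params()].
#' @return An `mrc_reference` with `source = "inferred"` and per-parameter
#'   support counts.
#' @export
infer_reference <- function(runs, names = default_audit_params()) {
  if (!length(runs)) stop("cannot infer a reference from zero runs")
  modality <- runs[[1]]$modality_label
  entries <- list()
  support <- integer()
  uninferable <- character()
  for (nm in names) {
    vals <- list()
    for (r in runs) {
      p <- r$parameters[[nm]]
      if (!is.null(p) && p$present) vals[[length(vals) + 1L]] <- p
    }
    if (!length(vals)) { uninferable <- c(uninferable, nm); next }
    keys <- vapply(vals, format_param_value, "")
    tab <- table(keys)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      if (vals[[1]]$kind == "numeric") {
        nums <- as.numeric(top)
        top <- top[which.min(nums)]
      } else {
        top <- sort(top, method = "radix")[1]
      }
    }
    winner <- vals[[match(top, keys)]]
    entries[[nm]] <- winner
    support[[nm]] <- as.integer(max(tab))
  }
  ref <- reference_protocol(modality, entries, source = "inferred",
                            support = support)
  attr(ref, "uninferable") <- uninferable
  ref
}

deviation_row <- function(run, parameter, reference, observed, type) {
  data.frame(run_id = run$run_id, subject_id = run$subject_id,
             session_id = run$session_id, parameter = parameter,
             reference = reference, observed = observed, type = type,
             stringsAsFactors = FALSE)
}

empty_deviations <- function() {
  data.frame(run_id = character(), subject_id = character(),
             session_id = character(), parameter = character(),
             reference = character(), observed = character(),
             type = character(), stringsAsFactors = FALSE)
}

#' Check one run against a reference protocol
#'
#' Emits one `mismatch` deviation per parameter outside tolerance and one
#' `missing` deviation per reference parameter the run lacks. An empty
#' result means the run is compliant.
#'
#' @param run an `mrc_run`.
#' @param ref an `mrc_reference` with at least one present entry.
#' @param tol an [tolerance_spec()] or plain fraction.
#' @return data.frame of deviations (possibly 0 rows).
#' @export
check_run <- function(run, ref, tol = tolerance_spec(0)) {
  stopifnot(inherits(run, "mrc_run"), inherits(ref, "mrc_reference"))
  present_entries <- Filter(function(p) p$present, ref$entries)
  if (!length(present_entries))
    stop("reference protocol has no parameters; refusing to audit")
  out <- empty_deviations()
  for (nm in sort(names(present_entries))) {
    rp <- present_entries[[nm]]
    op <- run$parameters[[nm]]
    if (is.null(op) || !op$present) {
      out <- rbind(out, deviation_row(run, nm, format_param_value(rp),
                                      NA_character_, "missing"))
    } else if (!value_compliant(op, rp, tol_for(tol, nm))) {
      out <- rbind(out, deviation_row(run, nm, format_param_value(rp),
                                      format_param_value(op), "mismatch"))
    }
  }
  out
}

#' Non-compliance and compliance percentages
#'
#' Full-precision percentages from subject counts; the compliant side is
#' the exact complement so the pair always sums to 100. Reports display
#' both truncated (not rounded) to 2 decimals, recomputing the compliant
#' side from its own count.
#'
#' @param n_noncompliant,n_total subject counts, `0 <= n_noncompliant <=
#'   n_total`, `n_total >= 1`.
#' @return list with `noncompliant_pct` and `compliant_pct` (full
#'   precision).
#' @export
noncompliance_percent <- function(n_noncompliant, n_total) {
  if (!is.numeric(n_total) || n_total < 1)
    stop("percentage undefined for n_total < 1")
  if (n_noncompliant < 0 || n_noncompliant > n_total)
    stop("need 0 <= n_noncompliant <= n_total")
  nc <- 100 * n_noncompliant / n_total
  list(noncompliant_pct = nc, compliant_pct = 100 - nc)
}

#' Format a percentage for display (truncation rule)
#'
#' Truncates toward zero at `decimals` places (64.4312 -> "64.43",
#' 35.5687 -> "35.56"); a tiny epsilon absorbs float noise so exact values
#' like 100 survive.
#'
#' @param x numeric percentage.
#' @param decimals digits to keep.
#' @return character scalar.
#' @export
format_pct <- function(x, decimals = 2) {
  f <- 10^decimals
  sprintf(paste0("%.", decimals, "f"), floor(x * f + 1e-9) / f)
}

pct_from_counts <- function(n, total, decimals = 2) {
  format_pct(100 * n / total, decimals)
}

#' Partition runs into strata
#'
#' Stratification keys: `vendor`, `ped` (phase-encoding direction token),
#' `entities` (BIDS differentiating entities), `echo_number`. Runs lacking
#' a key field fall into an `"unannotated"` stratum (e.g. field maps whose
#' header carries no PED annotation), keeping the partition exhaustive and
#' disjoint. An empty key set yields the identity stratification.
#'
#' @param runs list of runs.
#' @param keys character subset of
#'   `c("vendor", "ped", "entities", "echo_number")`.
#' @return Named list of run lists; names are `key=value` strings joined
#'   with `|`, or `"all"` for the identity stratification.
#' @export
stratify <- function(runs, keys = character()) {
  keys <- tolower(keys)
  bad <- setdiff(keys, c("vendor", "ped", "entities", "echo_number"))
  if (length(bad)) stop("unknown strata keys: ", paste(bad, collapse = ", "))
  if (!length(keys)) return(stats::setNames(list(runs), "all"))
  key_of <- function(r) {
    parts <- vapply(keys, function(k) {
      v <- switch(k,
        vendor = r$vendor,
        ped = {
          p <- r$parameters[["PhaseEncodingDirection"]]
          if (!is.null(p) && p$present) p$value else ""
        },
        entities = r$entities,
        echo_number = if (is.na(r$echo_number)) "" else as.character(r$echo_number))
      if (is.null(v) || is.na(v) || !nzchar(v)) v <- "unannotated"
      paste0(k, "=", v)
    }, "")
    paste(parts, collapse = "|")
  }
  ks <- vapply(runs, key_of, "")
  out <- split(runs, ks)
  out[sort(names(out), method = "radix")]
}

new_summary <- function(modality_label, stratum, subject_status, deviations,
                        reference, tolerance, low_support = FALSE) {
  n_total <- length(subject_status)
  n_nc <- sum(subject_status == "non-compliant")
  pc <- noncompliance_percent(n_nc, n_total)
  miss_only <- vapply(names(subject_status), function(s) {
    d <- deviations[deviations$subject_id == s, , drop = FALSE]
    nrow(d) > 0 && all(d$type == "missing")
  }, FALSE)
  structure(list(
    modality_label = modality_label,
    stratum = stratum,
    n_total = n_total,
    n_noncompliant = n_nc,
    n_compliant = n_total - n_nc,
    noncompliant_pct = pc$noncompliant_pct,
    compliant_pct = pc$compliant_pct,
    n_noncompliant_mismatch = n_nc - sum(miss_only),
    deviant_parameters = sort(unique(deviations$parameter)),
    subject_status = subject_status,
    deviations = deviations,
    reference = reference,
    tolerance = tolerance,
    low_support = low_support), class = "mrc_summary")
}

#' @export
print.mrc_summary <- function(x, ...) {
  cat(sprintf("<mrc_summary %s [%s]: %d/%d non-compliant (%s%%)%s>\n",
              x$modality_label, x$stratum, x$n_noncompliant, x$n_total,
              format_pct(x$noncompliant_pct),
              if (length(x$deviant_parameters))
                paste0(" params: ", paste(x$deviant_parameters, collapse = ","))
              else ""))
  invisible(x)
}

#' Horizontal audit: all subjects of one modality against a reference
#'
#' Runs are first stratified (vendor, PED, entities; an echo-number stratum
#' is added automatically when the modality is multi-echo, so legitimate
#' echo variation is never flagged). Within each stratum the reference is
#' either the supplied external protocol or inferred by majority vote, and
#' every run is checked; a subject is non-compliant as soon as any single
#' one of its runs deviates in any parameter. Missing parameters count
#' toward non-compliance but are typed separately, and
#' `n_noncompliant_mismatch` excludes subjects whose only deviations are
#' missing fields.
#'
#' @param h an `mrc_hierarchy`.
#' @param modality_label normalized label; must exist.
#' @param ref optional external `mrc_reference`; `NULL` infers per stratum.
#' @param tol [tolerance_spec()] or plain fraction.
#' @param strata_keys see [stratify()].
#' @param params parameter roster to audit.
#' @return List of `mrc_summary`, one per stratum.
#' @export
horizontal_audit <- function(h, modality_label, ref = NULL,
                             tol = tolerance_spec(0),
                             strata_keys = character(),
                             params = default_audit_params()) {
  rs <- runs_for(h, modality_label)
  if (!length(rs)) stop("modality not present in dataset: ", modality_label)
  if (!inherits(tol, "mrc_tolerance")) tol <- tolerance_spec(tol)
  echoes <- unique(stats::na.omit(vapply(rs, `[[`, NA_integer_, "echo_number")))
  if (length(echoes) > 1L && !"echo_number" %in% tolower(strata_keys))
    strata_keys <- c(strata_keys, "echo_number")
  strata <- stratify(rs, strata_keys)
  summaries <- list()
  for (sk in names(strata)) {
    srs <- strata[[sk]]
    sref <- if (is.null(ref)) infer_reference(srs, params) else ref
    devs <- empty_deviations()
    for (r in srs) devs <- rbind(devs, check_run(r, sref, tol))
    subj <- sort(unique(vapply(srs, `[[`, "", "subject_id")))
    status <- stats::setNames(
      ifelse(subj %in% devs$subject_id, "non-compliant", "compliant"), subj)
    low <- is.null(ref) && length(subj) == 1L
    if (low)
      message("stratum '", sk, "' of ", modality_label,
              " has a single subject; inferred reference has low support")
    summaries[[sk]] <- new_summary(modality_label, sk, status, devs, sref,
                                   tol$global_t, low_support = low)
  }
  summaries
}

#' Vertical audit: cross-modality consistency within one subject
#'
#' Two rule families, applied per session: (1) fieldmap geometry — every
#' fieldmap run's field of view, number of slices, slice thickness and
#' angulation must equal those of its paired EPI runs (BOLD/DWI) in the
#' same session, since a mismatched fieldmap cannot correct the EPI's
#' distortions; (2) shim consistency — the shim mode, a subject-specific
#' setting, must agree across all the subject's runs where it is known.
#' A subject with no fieldmap/EPI pair yields an empty geometry result.
#'
#' @param h an `mrc_hierarchy`.
#' @param subject_id subject to audit; must exist.
#' @param geometry geometry parameter roster.
#' @return data.frame with columns `subject_id`, `session_id`, `rule`,
#'   `modality_a`, `modality_b`, `parameter`, `value_a`, `value_b`
#'   (0 rows when fully consistent).
#' @export
vertical_audit <- function(h, subject_id, geometry = geometry_params()) {
  mods <- modalities_for(h, subject_id)
  if (!length(mods)) stop("subject not present in dataset: ", subject_id)
  srs <- Filter(function(r) r$subject_id == subject_id, runs_for_all(h))
  out <- data.frame(subject_id = character(), session_id = character(),
                    rule = character(), modality_a = character(),
                    modality_b = character(), parameter = character(),
                    value_a = character(), value_b = character(),
                    stringsAsFactors = FALSE)
  add <- function(ses, rule, ma, mb, parm, va, vb) {
    rbind(out, data.frame(subject_id = subject_id, session_id = ses,
                          rule = rule, modality_a = ma, modality_b = mb,
                          parameter = parm, value_a = va, value_b = vb,
                          stringsAsFactors = FALSE))
  }
  is_fmap <- function(r) grepl("FMAP", r$modality_label)
  is_epi <- function(r) grepl("BOLD|FUNC|DWI|DTI|EPI", r$modality_label) && !is_fmap(r)
  for (ses in unique(vapply(srs, `[[`, "", "session_id"))) {
    in_ses <- Filter(function(r) r$session_id == ses, srs)
    fmaps <- Filter(is_fmap, in_ses)
    epis <- Filter(is_epi, in_ses)
    if (!length(fmaps) || !length(epis)) {
      message("subject ", subject_id, " session ", ses,
              ": no fieldmap/EPI pair; geometry rule skipped")
      next
    }
    # one representative EPI run per EPI modality
    epi_labels <- vapply(epis, `[[`, "", "modality_label")
    reps <- epis[!duplicated(epi_labels)]
    for (fm in fmaps) for (ep in reps) {
      for (g in geometry) {
        pf <- fm$parameters[[g]]; pe <- ep$parameters[[g]]
        if (is.null(pf) || is.null(pe) || !pf$present || !pe$present) next
        if (!value_compliant(pf, pe, 0))
          out <- add(ses, "fieldmap-geometry", fm$modality_label,
                     ep$modality_label, g, format_param_value(pf),
                     format_param_value(pe))
      }
    }
  }
  # shim consistency across the subject's runs
  shims <- Filter(function(r) {
    p <- r$parameters[["ShimMode"]]
    !is.null(p) && p$present
  }, srs)
  if (length(shims) > 1L) {
    toks <- vapply(shims, function(r) r$parameters[["ShimMode"]]$value, "")
    tab <- table(toks)
    modal <- sort(names(tab)[tab == max(tab)], method = "radix")[1]
    for (r in shims[toks != modal]) {
      out <- add(r$session_id, "shim-consistency", r$modality_label, "*",
                 "ShimMode", r$parameters[["ShimMode"]]$value, modal)
    }
  }
  out
}

#' Non-compliance as a function of the tolerance level
#'
#' Infers (or accepts) one fixed reference for the modality, then re-audits
#' at each tolerance. The curve is non-increasing in `t` for numeric
#' deviations and flat when the only deviations are categorical or beyond
#' the largest tolerance.
#'
#' @param h an `mrc_hierarchy`.
#' @param modality_label modality to sweep.
#' @param t_values ascending tolerance fractions.
#' @param ref optional external reference; `NULL` infers once from all runs.
#' @param params parameter roster.
#' @return Named numeric vector: `t` -> non-compliant percentage (full
#'   precision).
#' @export
tolerance_sweep <- function(h, modality_label,
                            t_values = seq(0, 0.05, by = 0.01),
                            ref = NULL, params = default_audit_params()) {
  if (is.unsorted(t_values, strictly = FALSE))
    stop("t_values must be sorted ascending")
  if (is.null(ref))
    ref <- infer_reference(runs_for(h, modality_label), params)
  out <- stats::setNames(numeric(length(t_values)), as.character(t_values))
  for (i in seq_along(t_values)) {
    s <- horizontal_audit(h, modality_label, ref = ref, tol = t_values[i],
                          params = params)
    out[i] <- s[[1]]$noncompliant_pct
  }
  out
}

#' Audit every modality of a dataset
#'
#' Convenience wrapper used by the CLI and the monitor: one horizontal
#' audit per modality, flattened into a single summary list.
#'
#' @param h an `mrc_hierarchy`.
#' @param tol tolerance.
#' @param strata_keys see [stratify()].
#' @param ref optional external reference applied to its own modality only.
#' @param params parameter roster.
#' @return List of `mrc_summary`.
#' @export
audit_dataset <- function(h, tol = tolerance_spec(0),
                          strata_keys = character(), ref = NULL,
                          params = default_audit_params()) {
  out <- list()
  for (m in modalities(h)) {
    use_ref <- if (!is.null(ref) && identical(ref$modality_label, m)) ref else NULL
    ss <- horizontal_audit(h, m, ref = use_ref, tol = tol,
                           strata_keys = strata_keys, params = params)
    out <- c(out, ss)
  }
  out
}
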