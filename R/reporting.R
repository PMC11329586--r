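#' Assemble a compliance report
#'
#' Bundles per-modality-per-stratum summaries into the report object that
#' [render_report()] serializes. Row order is deterministic (modality, then
#' stratum); the timestamp is injectable so renders can be byte-identical.
#'
#' @param summaries list of `mrc_summary` from [horizontal_audit()] /
#'   [audit_dataset()].
#' @param dataset_name dataset label.
#' @param tolerance tolerance fraction used for the audit.
#' @param decimals display decimals for percentages (truncation rule).
#' @param timestamp report timestamp string; `NULL` uses the current UTC
#'   time.
#' @return An object of class `mrc_report`.
#' @export
compliance_report <- function(summaries, dataset_name = "dataset",
                              tolerance = 0, decimals = 2,
                              timestamp = NULL) {
  if (is.null(timestamp))
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ord <- order(vapply(summaries, `[[`, "", "modality_label"),
               vapply(summaries, `[[`, "", "stratum"), method = "radix")
  summaries <- summaries[ord]
  rows <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      modality = s$modality_label,
      stratum = s$stratum,
      n_noncompliant = s$n_noncompliant,
      pct_noncompliant = pct_from_counts(s$n_noncompliant, s$n_total, decimals),
      n_total = s$n_total,
      deviant_params = paste(s$deviant_parameters, collapse = ";"),
      n_compliant = s$n_compliant,
      pct_compliant = pct_from_counts(s$n_compliant, s$n_total, decimals),
      stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame()
  devs <- do.call(rbind, c(list(empty_deviations()),
                           lapply(summaries, `[[`, "deviations")))
  miss <- devs[devs$type == "missing", , drop = FALSE]
  missing_roster <- if (nrow(miss)) {
    agg <- stats::aggregate(run_id ~ parameter, data = miss,
                            FUN = function(x) length(unique(x)))
    names(agg) <- c("parameter", "n_runs_missing")
    agg[order(agg$parameter), , drop = FALSE]
  } else data.frame(parameter = character(), n_runs_missing = integer())
  structure(list(dataset_name = dataset_name, timestamp = timestamp,
                 tolerance = tolerance, decimals = decimals, rows = rows,
                 summaries = summaries, deviations = devs,
                 missing_roster = missing_roster,
                 repeat_offenders = repeat_offenders(summaries)),
            class = "mrc_report")
}

#' Subjects non-compliant in two or more parameters
#'
#' Repeat offenders often indicate a systematic cause — e.g. a subject
#' whose TR was raised and flip angle lowered together points at an SAR
#' adjustment during the session — so they are listed separately.
#'
#' @param summaries list of `mrc_summary`.
#' @return Named list: subject id -> sorted character vector of deviant
#'   parameter names (only subjects with >= 2 distinct parameters).
#' @export
repeat_offenders <- function(summaries) {
  devs <- do.call(rbind, c(list(empty_deviations()),
                           lapply(summaries, `[[`, "deviations")))
  if (!nrow(devs)) return(list())
  by_subj <- split(devs$parameter, devs$subject_id)
  by_subj <- lapply(by_subj, function(p) sort(unique(p)))
  by_subj <- by_subj[vapply(by_subj, length, 0L) >= 2L]
  by_subj[sort(names(by_subj), method = "radix")]
}

report_payload <- function(report) {
  # reports reconstructed from a saved JSON audit re-emit their original
  # payload verbatim
  if (!is.null(report$payload)) return(report$payload)
  list(
    dataset = report$dataset_name,
    timestamp = report$timestamp,
    tolerance = report$tolerance,
    rows = lapply(seq_len(nrow(report$rows)), function(i) {
      r <- report$rows[i, ]
      s <- report$summaries[[i]]
      list(modality = r$modality, stratum = r$stratum,
           n_noncompliant = r$n_noncompliant,
           pct_noncompliant = r$pct_noncompliant,
           noncompliant_pct_full = s$noncompliant_pct,
           n_total = r$n_total,
           deviant_params = s$deviant_parameters,
           n_compliant = r$n_compliant,
           pct_compliant = r$pct_compliant,
           compliant_pct_full = s$compliant_pct,
           n_noncompliant_mismatch = s$n_noncompliant_mismatch,
           low_support = s$low_support)
    }),
    missing_parameters = lapply(seq_len(nrow(report$missing_roster)), function(i) {
      as.list(report$missing_roster[i, ])
    }),
    repeat_offenders = report$repeat_offenders,
    deviations = lapply(seq_len(nrow(report$deviations)), function(i) {
      as.list(report$deviations[i, ])
    }))
}

render_text <- function(report) {
  lines <- c(
    sprintf("Protocol compliance report: %s", report$dataset_name),
    sprintf("Generated: %s   tolerance t = %s", report$timestamp,
            format(report$tolerance)),
    "")
  if (!nrow(report$rows)) return(paste(c(lines, "Nothing audited."), collapse = "\n"))
  hdr <- sprintf("%-28s %-28s %6s %8s %6s %8s  %s",
                 "modality", "stratum", "#nc", "%nc", "#tot", "%ok", "deviant parameters")
  lines <- c(lines, hdr, strrep("-", nchar(hdr)))
  for (i in seq_len(nrow(report$rows))) {
    r <- report$rows[i, ]
    lines <- c(lines, sprintf("%-28s %-28s %6d %8s %6d %8s  %s",
                              r$modality, r$stratum, r$n_noncompliant,
                              r$pct_noncompliant, r$n_total, r$pct_compliant,
                              r$deviant_params))
  }
  if (nrow(report$missing_roster)) {
    lines <- c(lines, "", "Missing parameters (runs lacking a reference field):")
    for (i in seq_len(nrow(report$missing_roster))) {
      m <- report$missing_roster[i, ]
      lines <- c(lines, sprintf("  %-28s missing in %d run(s)",
                                m$parameter, m$n_runs_missing))
    }
  }
  if (length(report$repeat_offenders)) {
    lines <- c(lines, "", "Repeat offenders (non-compliant in >= 2 parameters):")
    for (s in names(report$repeat_offenders)) {
      lines <- c(lines, sprintf("  %-16s %s", s,
                                paste(report$repeat_offenders[[s]], collapse = ", ")))
    }
  }
  paste(lines, collapse = "\n")
}

render_tsv <- function(report) {
  cols <- c("modality", "stratum", "n_noncompliant", "pct_noncompliant",
            "n_total", "deviant_params", "n_compliant", "pct_compliant")
  if (!nrow(report$rows))
    return(paste(cols, collapse = "\t"))
  con <- textConnection("tsv_out", "w", local = TRUE)
  utils::write.table(report$rows[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paste(tsv_out, collapse = "\n")
}

render_html <- function(report) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- if (!nrow(report$rows)) "<p>Nothing audited.</p>" else {
    cells <- vapply(seq_len(nrow(report$rows)), function(i) {
      r <- report$rows[i, ]
      sprintf(paste0("<tr><td>%s</td><td>%s</td><td>%d</td><td>%s</td>",
                     "<td>%d</td><td>%s</td><td>%d</td><td>%s</td></tr>"),
              esc(r$modality), esc(r$stratum), r$n_noncompliant,
              r$pct_noncompliant, r$n_total, esc(r$deviant_params),
              r$n_compliant, r$pct_compliant)
    }, "")
    paste0("<table><thead><tr><th>Modality</th><th>Stratum</th>",
           "<th>#Non-compliant</th><th>%Non-compliant</th><th>Total</th>",
           "<th>Deviant parameters</th><th>#Compliant</th>",
           "<th>%Compliant</th></tr></thead><tbody>",
           paste(cells, collapse = ""), "</tbody></table>")
  }
  offenders <- if (length(report$repeat_offenders)) {
    items <- vapply(names(report$repeat_offenders), function(s) {
      sprintf("<li><b>%s</b>: %s</li>", esc(s),
              esc(paste(report$repeat_offenders[[s]], collapse = ", ")))
    }, "")
    paste0("<h2>Repeat offenders</h2><ul>", paste(items, collapse = ""), "</ul>")
  } else ""
  paste0("<!DOCTYPE html><html><head><meta charset='utf-8'>",
         "<title>Compliance report: ", esc(report$dataset_name), "</title>",
         "<style>body{font-family:sans-serif;margin:2em}",
         "table{border-collapse:collapse}td,th{border:1px solid #999;",
         "padding:4px 8px}th{background:#eee}</style></head><body>",
         "<h1>Protocol compliance report: ", esc(report$dataset_name), "</h1>",
         "<p>Generated ", esc(report$timestamp), " &mdash; tolerance t = ",
         format(report$tolerance), "</p>", body, offenders, "</body></html>")
}

#' Render a compliance report
#'
#' Deterministic given identical inputs (inject `timestamp` in
#' [compliance_report()] for byte-identical output). JSON carries counts
#' and full-precision percentages so it round-trips exactly; TSV uses the
#' fixed column set `modality, stratum, n_noncompliant, pct_noncompliant,
#' n_total, deviant_params, n_compliant, pct_compliant`; HTML is fully
#' self-contained (no external assets).
#'
#' @param report an `mrc_report`.
#' @param format one of `"text"`, `"json"`, `"tsv"`, `"html"`.
#' @param path optional output file.
#' @return The rendered document as a character scalar (invisibly when
#'   written to `path`).
#' @export
render_report <- function(report, format = c("text", "json", "tsv", "html"),
                          path = NULL) {
  stopifnot(inherits(report, "mrc_report"))
  format <- match.arg(format)
  doc <- switch(format,
    text = render_text(report),
    tsv = render_tsv(report),
    html = render_html(report),
    json = as.character(jsonlite::toJSON(report_payload(report),
                                         auto_unbox = TRUE, digits = I(17),
                                         null = "null", pretty = TRUE)))
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' @export
print.mrc_report <- function(x, ...) {
  cat(render_text(x), "\n")
  invisible(x)
}
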