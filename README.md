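# mrcompliance

Acquisition-protocol compliance auditing for MR imaging metadata.

Multi-site MRI studies depend on every scanner acquiring with the same
physics parameters — repetition time (TR), echo time (TE), flip angle (FA),
phase-encoding direction (PED), pixel bandwidth, and so on. In practice
those values drift: technologists adjust protocols per patient (e.g. SAR
limits force a lower flip angle and longer TR together), software updates
reset console defaults, and vendors implement the "same" sequence
differently. Undetected, such deviations change tissue contrast, break
fieldmap-based EPI distortion correction, and bias every downstream
statistic. `mrcompliance` finds them automatically, straight from the
acquisition metadata.

## What it does

* **Parses** a DICOM tree (any on-disk layout — runs are grouped by
  `SeriesInstanceUID`, never by folder names) or a BIDS dataset (JSON
  sidecars) into a modality / subject / session / run hierarchy. Siemens
  ASCCONV private headers yield shim mode, parallel imaging (iPAT) and
  multi-slice mode; GE/Philips private headers are skipped.
* **Builds a reference protocol** per modality, either loaded from a flat
  XML export (`<protocol modality="..."><param name="..." value="..."/>`)
  or inferred by majority vote: the modal value of each parameter across
  runs, with deterministic tie-breaking.
* **Horizontal audit** — every subject within a modality is checked against
  the reference. For a numeric parameter with reference value `R` and
  tolerance level `t`, an observed value is compliant inside the closed
  interval `R ± t·R`; categorical parameters (e.g. PED) must match exactly
  at every `t`. A subject is non-compliant as soon as a single run deviates
  in a single parameter, and per-stratum scores are

      non-compliant % = 100 · (# non-compliant subjects) / (# subjects)
      compliant %     = 100 − non-compliant %

  with stratification by vendor, PED, or BIDS entities (and automatically
  by echo number for multi-echo series).
* **Vertical audit** — within one subject, fieldmaps must match their EPI's
  geometry (field of view, number of slices, slice thickness, angulation),
  and the subject-specific shim mode must agree across runs.
* **Reports** in text, TSV, JSON and self-contained HTML, including the
  missing-parameter roster and "repeat offenders" (subjects deviant in ≥ 2
  parameters). Percentages are *truncated*, not rounded, at 2 decimals.
* **Monitors** a growing DICOM archive incrementally: a JSON state file
  fingerprints files already parsed, and each audit is provably identical
  to a from-scratch rescan of the current tree.
* **Generates synthetic datasets** (valid tiny DICOM files and/or BIDS
  trees) from a known base protocol with controlled deviation injection
  and a ground-truth manifest, so the whole pipeline is testable offline.

## Worked example

```r
library(mrcompliance)

cfg <- fixture_config(
  n_subjects = 6, vendor_mix = c(SIEMENS = 1), seed = 7,
  deviations = list(
    deviation_spec("EchoTime", "numeric-shift", p = 0.3, factor = 1.2,
                   modalities = "anat_T1w"),
    deviation_spec("PhaseEncodingDirection", "categorical-flip", p = 0.2,
                   alternate = "PA", modalities = "func_task-rest_bold")))
td <- tempfile()
generate_fixture(cfg, td, format = "dicom")

h <- scan_dicom_tree(file.path(td, "dicom"))
rep <- compliance_report(audit_dataset(h), "demo", tolerance = 0,
                         timestamp = "2026-01-01T00:00:00Z")
cat(render_report(rep, "text"))
```

prints

```
Protocol compliance report: demo
Generated: 2026-01-01T00:00:00Z   tolerance t = 0

modality                     stratum                         #nc      %nc   #tot      %ok  deviant parameters
-------------------------------------------------------------------------------------------------------------
ANAT_T1W                     all                               1    16.66      6    83.33  EchoTime
FMAP_DIR_AP_EPI              all                               0     0.00      6   100.00  
FUNC_TASK_REST_BOLD          all                               1    16.66      6    83.33  PhaseEncodingDirection
```

One of six subjects carries the injected 20 % echo-time shift in the T1w
scan (16.66 % = truncated 100/6) and one carries the flipped
phase-encoding direction in the BOLD run; the untouched fieldmap modality
is fully compliant. Re-auditing with `tol = 0.25` accepts the numeric
shift but still flags the categorical flip — tolerance never applies to
tokens.

The same audit is available from the shell:

```sh
Rscript inst/cli/mrcompliance audit --data-root /data/dicom \
    --tolerance 0.05 --strata vendor,ped --output-dir reports \
    --fail-on-noncompliance     # exit 3 when anything deviates (CI-friendly)
Rscript inst/cli/mrcompliance monitor --data-root /data/dicom \
    --state-file state.json --output-dir reports   # cron-friendly increments
```

## Layout

```
R/                 implementation (hierarchy, DICOM codec, readers,
                   compliance engine, reporting, monitoring, CLI, generator)
tests/testthat/    unit + property + acceptance suites
scripts/acceptance.R
vignettes/protocol-compliance.Rmd   methods notes
inst/cli/mrcompliance               Rscript CLI wrapper
```
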