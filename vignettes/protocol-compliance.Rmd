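---
title: "Auditing MR acquisition protocols with mrcompliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing MR acquisition protocols with mrcompliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcompliance)
```

## The model

An MR dataset is a set of *runs* — one acquired series each — organised
along two axes: modality-first (modality → subject → session → runs) and
subject-first (subject → modality → runs). `mrcompliance` keeps a single
run set and derives both views from it, so the two traversals can never
disagree and insertion order is irrelevant. Runs are grouped into
modalities by their normalized sequence name (protocol name for DICOM;
datatype + differentiating entities + suffix for BIDS), never by file
layout: folder conventions vary wildly across sites and carry no
acquisition semantics.

Two audits operate on this structure.

**Horizontal audit.** Each modality's runs are compared against a
*reference protocol*: one expected value per audited parameter. Given a
numeric reference value $R$ and a tolerance level $t \in [0,1]$, an
observed value $x$ is compliant iff

$$x \in [\,R - tR,\; R + tR\,]$$

with both bounds inclusive. Categorical parameters (phase-encoding
direction, sequence variant, shim mode, parallel-imaging mode) must match
token-for-token at every $t$ — a flipped PED is a different acquisition,
not a small error. A subject is non-compliant as soon as *any one* of its
runs deviates in *any one* parameter; per-stratum scores are

$$\text{non-compliant \%} = \frac{100 \times \#\text{non-compliant
subjects}}{\#\text{subjects}}, \qquad
\text{compliant \%} = 100 - \text{non-compliant \%}.$$

**Vertical audit.** Within a subject, a fieldmap can only correct an EPI's
susceptibility distortions if it was acquired with the same geometry, so
each fieldmap run is compared to its session's EPI runs on field of view,
number of slices, slice thickness and angulation. The shim mode is a
subject-specific adjustment and is additionally checked for consistency
across all of the subject's runs.

## Reference protocols

When a scanner-exported protocol is available it should be used: the
package reads a flat XML schema
(`<protocol modality="..."><param name="..." value="..." units="..."/></protocol>`).
Vendor-proprietary binary protocol formats are out of scope, and the flat
schema is this package's own convention.

Without an export, the reference is *inferred by majority vote*: for each
parameter, the modal value over the runs where it is present. Absent
values never vote. Ties break to the smallest numeric value or the
lexicographically smallest token — an arbitrary but total order, chosen so
inference is reproducible and independent of run order. The per-parameter
support (how many runs agreed) is recorded, and single-subject strata are
flagged low-support.

Majority-vote inference assumes deviants are a minority *within each
audited stratum*. If, say, a quarter of subjects are injected with a
deviation and the smallest vendor stratum happens to collect most of them,
the inferred reference can flip to the deviant value; that is a property
of the estimator, not a defect. The test suite therefore validates exact
injection recovery in single-vendor worlds and exercises mixed-vendor
behaviour (stratification, unannotated strata, vendor unit rules) with
small deviation fractions.

## Parameters, units, vendors

The controlled vocabulary (`param_vocabulary()`) fixes each parameter's
kind and unit: TR/TE in ms (BIDS sidecar seconds are converted at read
time), flip angle in degrees, pixel bandwidth in Hz/pixel, field strength
in T, geometry in mm. GE consoles report field of view in cm where
Siemens/Philips use mm; the DICOM reader normalizes this by vendor. The
default audit roster — TR, TE, FA, PED, pixel bandwidth, echo train
length, phase-encoding steps, shim mode, parallel imaging, sequence
variant, field strength — covers the parameters most often implicated in
protocol drift, and is user-extensible via the `params` argument of the
audit functions.

Phase-encoding direction is stored source-natively (anatomical tokens in
DICOM headers, `i/j/k±` axis tokens in BIDS) because no standard
cross-dialect mapping exists; `normalize_ped()` applies the package's own
axial-acquisition convention (`j-`→AP, `j`→PA, …) and is used only when
comparing runs read from different sources.

Shim mode, parallel imaging and multi-slice mode have no public DICOM tag.
They are read from the Siemens ASCCONV private block when present;
GE/Philips private headers use undocumented binary layouts and are
deliberately skipped, so runs from those vendors simply lack these
parameters and show up in missing-parameter reporting when a reference
expects them.

## Numerical choices

* **t = 0 equality.** "Absolute equivalence" cannot mean bit equality
  across serialization formats (DICOM decimal strings vs JSON doubles), so
  zero tolerance compares within an absolute epsilon of 1e-6 in the
  parameter's native unit.
* **Inclusive bounds.** An observation exactly at $R \pm tR$ is compliant;
  a 1e-9 relative slack absorbs the floating-point representation of the
  bounds themselves.
* **Truncation display.** Percentages are truncated toward zero at two
  decimals (541/1521 prints 35.56, not 35.57), and the compliant side is
  recomputed from its own count rather than as `100 − x`; at full
  precision the pair sums to exactly 100. Acceptable-range *bounds* are
  displayed rounded (6.66 × 1.05 prints 6.99; 6.66 × 0.95 prints 6.33).
* **Missing parameters** count toward non-compliance but are typed
  `missing`, reported in their own roster, and excluded from the
  `n_noncompliant_mismatch` tally — both readings of "non-compliant"
  remain recoverable from every report.
* **Multi-echo.** Audits add an echo-number stratum automatically whenever
  a modality contains more than one echo, so legitimate echo variation is
  never flagged.
* **Intentional protocol changes over time** are not modelled; audit
  subsets of the dataset against a single fixed reference instead.

## The synthetic generator

`generate_fixture()` emits a stated world: valid (tiny) DICOM Part-10
files — explicit little-endian, a 2×2 token pixel payload, a Siemens-style
ASCCONV block for Siemens runs — and/or a BIDS tree with JSON sidecars,
from a configurable base protocol. The defaults are a typical 3T research
session (MPRAGE-like T1w at TR 2300 ms/TE 2.98 ms/FA 9°, a task-rest BOLD
EPI at TR 800 ms/TE 30 ms/FA 52°, and a fieldmap sharing the BOLD
geometry) with a Siemens-heavy vendor mix (60/25/15) echoing large
multi-site studies. Deviations are injected per `deviation_spec()`:
numeric shifts, categorical flips, or dropped fields, applied to the first
⌊p·n⌋ subjects of a seeded shuffle so the manifest records the exact
ground truth. Everything is reproducible from the seed, down to
byte-identical manifests.

What the generator does *not* emulate: real anatomy or k-space physics
(audits never read pixels), GE/Philips private-header encodings,
compressed transfer syntaxes, DICOM sequence (SQ) elements, or the
long-tailed messiness of real-world sidecars. A green injection-recovery
test therefore establishes that the audit engine is exact on well-formed
metadata with known truth — not that every conceivable vendor quirk is
handled.

## Incremental monitoring

`incremental_audit()` fingerprints every file (size + md5) in a JSON state
file and caches the parsed per-file record. Each invocation re-derives the
hierarchy from the cache restricted to files currently on disk — new files
are parsed, deleted files drop out — so the incremental report is
*identical* to a from-scratch rescan, which the tests assert over growth
and deletion sequences. The cache only accelerates header reads; it never
owns the truth. Scheduling is left to cron/systemd: the CLI `monitor`
subcommand is a single idempotent invocation.

## Known limitations

* The in-package DICOM codec reads only explicit-VR little-endian Part-10
  files with flat datasets — sufficient for metadata audits and the
  synthetic world, but not a general DICOM implementation (this
  environment offers no DICOM library to build on).
* Cross-vendor sequence equivalence (e.g. matching a Siemens SPACE to a
  Philips VISTA acquisition) is out of scope; stratify by vendor instead.
* No pixel-level QA (motion, artifacts) and no statistical harmonization —
  this package tells you *that* and *where* acquisition parameters drifted,
  which is the precondition for both.
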