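Package: mrcompliance
Title: Acquisition-Protocol Compliance Auditing for MR Imaging Metadata
Version: 0.1.0
Authors@R:
    person("mrcompliance", "developers", email = "mrcompliance@example.org",
           role = c("aut", "cre"))
Description: Audits magnetic-resonance acquisition metadata for protocol
    compliance. Parses DICOM trees and BIDS datasets into a
    modality/subject/session/run hierarchy without relying on directory
    layout, infers a reference protocol by majority vote (or loads one from
    a flat XML export), runs horizontal audits (all subjects within a
    modality against the reference, with numeric tolerance bands) and
    vertical audits (cross-modality geometry and shim consistency within a
    subject), and renders compliance reports in text, TSV, JSON and HTML.
    Includes an incremental monitoring mode for growing DICOM archives and
    a synthetic dataset generator with controlled deviation injection so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
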