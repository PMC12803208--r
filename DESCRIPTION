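Package: framefp
Title: Single-Frame Functional Connectome Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Phase-coherence dynamic functional connectivity and
    single-volume connectome fingerprinting for node-level BOLD time
    series. Computes per-volume phase-coherence matrices via the Hilbert
    transform, represents each volume by the leading eigenvector of its
    coherence matrix, and identifies the subject (or task) of a target
    scan by matching single volumes against a labeled database of scans.
    Includes a synthetic multi-subject cohort generator with controllable
    subject, task and session structure, node-level preprocessing
    (steady-state trimming, band-pass filtering, confound regression,
    motion flagging, tSNR), permutation nulls for identification
    accuracy, database-size and node-count sweeps, subnetwork-stratified
    node down-sampling, motion-split accuracy, and a static-network
    fingerprinting baseline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
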