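Package: biwave
Title: Bidirectional Wavefront Sequence Alignment with a Two-Tier Memory Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact pairwise sequence alignment under edit penalties using the
    wavefront algorithm (WFA) and its bidirectional variant (BiWFA), restructured
    as an iterative, memory-budgeted pipeline: pairs are split at breakpoints
    found by bidirectional search until each segment fits a fast-memory base-case
    budget, base cases are solved by classic WFA with full traceback, and partial
    CIGARs are assembled in order. A logical two-tier memory model (fast scratch
    versus bulk memory) counts block and element transfers, making kernel fusion,
    wavefront spilling, reverse sequence reads and adaptive transfer sizing
    measurable in software. A batch scheduler with dynamic pair assignment,
    score-cap interruption and hybrid recovery executes whole datasets, and a
    synthetic pair generator reproduces fixed-length, fixed-error-rate workloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
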