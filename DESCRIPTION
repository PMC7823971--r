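Package: gcprofiler
Title: Compositional Cytogenomics Profiling of Soft-Masked Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies and visualizes GC content and soft-masked repeat
    content in consecutive non-overlapping windows along chromosome-level
    genome assemblies. Reads soft-masked FASTA (plain or gzip), computes
    per-window GC%, repeat% and per-fraction GC% (repeats vs unique DNA),
    persists per-chromosome profile tables, renders chromosome-scale
    dual-mode color plots (repeat-density coloring, or the swapped mode
    mimicking CMA3/CDD fluorescence banding), and tests the pooled
    association between GC% and repeat% per assembly. Includes a
    deterministic synthetic-assembly generator with preset repeat
    architectures so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
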