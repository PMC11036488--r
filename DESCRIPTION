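Package: loxkit
Title: Genotyping Toolkit for SCRaMbLEd Synthetic Chromosomes
Version: 0.1.0
Authors@R: person("loxkit", "developers", role = c("aut", "cre"),
    email = "loxkit@example.org")
Description: Design and interpretation of junction-spanning diagnostic qPCR
    assays for synthetic chromosomes carrying loxPsym recombination sites.
    Provides loxP-unit segmentation and signed arrangements, motif-spanning
    primer design with nearest-neighbor thermodynamics and exhaustive
    off-target screening, mismatch-tolerant in-silico end-point PCR, a
    Cre/loxPsym rearrangement simulator with replayable truth logs, and
    pattern-based candidate event calling with diversity-driven isolate
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    pheatmap,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
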