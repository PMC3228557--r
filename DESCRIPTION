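Package: promscan
Title: Promoter Motif Scanning, Co-Occurrence and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans transcription start site (TSS)-anchored upstream
    (promoter) sequences for transcription factor binding sites described
    either as bracketed degenerate consensus strings or as TRANSFAC-format
    position weight matrices, using a min-max-normalized additive
    similarity score on both strands. Summarizes site positions in fixed
    windows upstream of the TSS, finds co-occurrences of a secondary motif
    within a fixed distance of an anchor motif's sites, and tests gene-set
    over-representation of motifs and of flat annotation terms with the
    cumulative hypergeometric test, the 2x2 chi-square test and
    Benjamini-Hochberg false discovery rate control. Includes preparation
    of differential gene lists from fold-change/p-value tables, a
    synthetic promoter simulator that plants motifs with known ground
    truth so every stage can be validated end to end, and a pipeline
    driver with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
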