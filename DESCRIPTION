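Package: mhindex
Title: Microbial Habitability Profiling from Environment-Labelled 16S rRNA References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact, environment-labelled reference collections of 16S
    rRNA sequences from amplicon/metagenomic reads (quality, adapter, ambiguity
    and homopolymer filtering; 99% near-duplicate removal; k-mer rRNA
    screening; two-parent chimera detection; greedy 97% identity clustering
    within each environmental category) and profiles the habitability of a
    query prokaryote as Microbial Habitability Indices (MHIs): per-environment
    hit counts above 97/95/90/85/80% identity, weighted by an inverse-
    document-frequency style factor log(R_total/R(e)) and normalized to
    percentages. Includes a seeded local-alignment search with Karlin-Altschul
    e-values, a ground-truthed synthetic read generator for end-to-end
    validation, and command-line entry points for reference building,
    querying, and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
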