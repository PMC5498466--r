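Package: tascreen
Title: Detection and Characterization of Type II Toxin-Antitoxin Systems
    in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("tascreen", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A screening pipeline for chromosomal type II toxin-antitoxin
    (TA) operons in annotated bacterial genomes, developed around estuarine
    picocyanobacteria. Clusters a reference set of toxin and antitoxin
    proteins into families (single-linkage on local-alignment coverage and
    score density), assigns genome proteins to families by best
    Smith-Waterman hit under a Karlin-Altschul E-value cutoff, calls TA
    operons from co-directed adjacent gene pairs of complementary roles,
    and characterizes candidates by molecular weight, isoelectric point,
    open-reading-frame overlap (transcriptional coupling) and genomic-island
    context. Includes a stress-expression readout (specific growth rate,
    log2 fold changes, permutation significance, toxin:antitoxin ratio)
    and a synthetic-genome and count-table generator with planted ground
    truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
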