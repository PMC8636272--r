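Package: sedapipe
Title: Sedimentary Ancient DNA Metagenomics: Simulation, Classification,
    Authentication and Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for ancient environmental DNA (sedaDNA)
    metagenomics. Simulates degraded sedimentary DNA (short fragments with
    terminal cytosine-deamination damage) against synthetic multi-rank
    taxonomies and reference genomes; classifies reads by lowest common
    ancestor over perfect-identity alignments with exclusive-alignment
    confirmation, laboratory-control subtraction and checklist filtering;
    authenticates detections from terminal C-to-T / G-to-A damage profiles;
    evaluates reference-database representation with canonical k-mer
    coverage; corrects taxon abundances for identification efficiency;
    computes community diversity, binned beta-diversity turnover and
    non-metric multidimensional scaling; and places degraded read sets onto
    a mitochondrial phylogeny by branch-diagnostic SNP support and conflict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
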