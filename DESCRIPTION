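Package: plastome
Title: Chloroplast Genome Analysis: Structure, Diversity, Codon Usage and Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for annotated chloroplast (plastid) genomes: GenBank and
    FASTA input/output with circular-coordinate feature handling, annotation
    quality checks and genome statistics, detection of the quadripartite
    LSC/IRb/SSC/IRa structure by seed-and-extend inverted-repeat search,
    sequence orientation normalization, batch nucleotide diversity (pi) over
    shared gene and intergenic-spacer regions, relative synonymous codon
    usage (RSCU), microsatellite (SSR) and long-repeat (LSR) detection with
    genomic-context localization, shared-gene supermatrix preparation for
    phylogenetics, and conversion to NCBI tbl and mVISTA annotation formats.
    Includes a deterministic synthetic-plastome generator with a
    machine-readable truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
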