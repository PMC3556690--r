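Package: proteoshift
Title: Impact Analysis for Protein Sequence Database Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the consequences of replacing one protein
    sequence database by another in mass-spectrometry proteomics. Reads IPI-
    and UniProtKB-dialect FASTA, maps source identifiers onto the target by
    embedded cross-references and by exact sequence identity, performs in
    silico tryptic digestion (Keil rule, configurable missed cleavages),
    compares the distinct theoretical peptide search spaces, computes the
    remaining detectable sequence of proteins affected by lost peptides, and
    applies repository-evidence inclusion rules (proteotypic flags,
    experiment-count thresholds) to the lost peptides. A synthetic-data
    generator with a truth manifest supports end-to-end validation without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
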