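Package: circvirome
Title: Discovery and Typing of Circular DNA Viruses from Metagenomic Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for recovering small circular DNA virus genomes
    (papillomaviruses and CRESS-DNA viruses) from de novo metagenomic
    assemblies. Assemblers linearize circular templates and leave an exact
    terminal redundancy; circvirome detects and trims that redundancy,
    truncates low-complexity dinucleotide runs, and reduces each circle to a
    canonical rotation-and-strand representative. On the circularized
    genomes it scans for the conserved rolling-circle replication origin (a
    nonanucleotide motif presented in the loop of an inverted-repeat
    hairpin), calls open reading frames in six frames with full awareness of
    the circular breakpoint, computes all-vs-all pairwise-identity matrices
    and sliding-window identities, and applies the papillomavirus L1
    type/subtype/variant demarcation rule. A synthetic-contig generator with
    a machine-readable truth table supports end-to-end validation of every
    step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
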