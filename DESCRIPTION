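Package: junctionr
Title: Staggered-Cleavage-Aware Analysis of CRISPR Dual-sgRNA Junction
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes amplicon sequencing reads spanning the ligation
    junctions of Cas9 dual-sgRNA chromosomal rearrangements (DNA-fragment
    deletions, inversions and duplications). Reads are decomposed by a
    two-level dynamic-programming aligner into a left segment mapped to the
    upstream arm, an unmapped middle insertion, and a right segment mapped
    to the downstream arm, with a permitted overlap that captures the 1-3 nt
    5' overhangs of staggered Cas9 cleavage. Per-read outcomes are
    classified into precise ligations, deletions (1 bp, 2-20 bp, 21-100 bp,
    and >100 bp large resections), templated and untemplated insertions and
    indels; large resections are also called from two-segment mappings by
    segment order and strand. Includes Arratia-Waterman bounds on the
    probability of flanking microhomology as a function of deletion size,
    Monte-Carlo validation of the asymptotic longest-common-substring
    ratio, and a ground-truth read simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    tibble,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
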