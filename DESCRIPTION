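Package: mitoray
Title: Mitogenome Characterization for Freshwater Stingrays and Other Vertebrates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the complete desk-scale characterization of a
    vertebrate mitochondrial genome: annotation-table parsing and coordinate
    validation, base composition and AT/GC strand-skew statistics, codon
    usage (RSCU and the effective number of codons under the vertebrate
    mitochondrial genetic code, including incomplete stop codons), tandem
    repeat detection in the control region, cross-species gene-order
    (breakpoint) comparison, a pairwise Nei-Gojobori (1986) dN/dS selection
    screen, and distance-based neighbor-joining phylogeny with bootstrap
    support and monophyly assessment. A synthetic mitogenome generator and
    a tree-guided sequence evolver make every stage runnable and testable
    without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
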