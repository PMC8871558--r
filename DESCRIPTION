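Package: CSIscan
Title: Discovery of Conserved Signature Indels in Protein Alignments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects conserved signature indels (CSIs) - fixed-length,
    clade-specific insertions and deletions in conserved regions of protein
    multiple sequence alignments - and classifies their clade specificity,
    exception species and insertion/deletion polarity against a hierarchical
    clade partition with designated outgroups. Includes a desk-scale
    supermatrix phylogeny stage (concatenation, conserved-block trimming,
    site-coverage filtering, Poisson-corrected distances, neighbor joining
    with bootstrap support and outgroup rooting), a dash-notation signature
    figure renderer, a sequence-evolution simulator with planted indels and
    ground-truth scoring, and a packaged catalog of published rodent/Glires
    CSIs with per-clade tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phytools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
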