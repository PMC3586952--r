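Package: phylopos
Title: Phylogenomic Placement Diagnostics for Deep Fungal Divergences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the phylogenetic position of a fast-evolving
    clade from whole-genome data. Implements conserved gene-neighborhood
    (microsynteny) scoring under relaxed and strict definitions with
    correction for lineage-specific segmental duplications; a genome-wide
    gene-tree census that roots trees by the most distant outgroup, labels
    duplication and speciation nodes by species overlap, and classifies the
    sister group of a focal clade; duplication-minimizing supertree search by
    gene-tree/species-tree reconciliation; concatenated-alignment
    stratification by discrete-gamma site rate and clade variability with
    fastest-site removal and reduced-alphabet recoding; RELL-based topology
    tests (AU, BP, NP, PP, KH, SH, WKH, WSH) with confidence sets; and
    long-branch-attraction diagnostics via random-sequence replacement and
    parametric simulation. A synthetic-data generator with planted ground
    truth (species trees, gene orders, duplication-loss gene trees,
    alignments with rate heterogeneity) supports validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
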