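Package: mitocompr
Title: Comparative Analysis of Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes, built around the highly rearranged mitogenomes
    of thrips (Thysanoptera) but applicable to any compact animal
    mitogenome.  Provides circular intergenic/overlap accounting from a
    feature table, base composition and AT/GC strand-asymmetry skews per
    gene class, codon usage and relative synonymous codon usage (RSCU)
    under the invertebrate mitochondrial code, control-region
    tandem-repeat and motif detection, signed gene-order rearrangement
    analysis against the ancestral insect gene order (adjacencies,
    orientation changes, breakpoint distances, common intervals, and
    exact small-scale event-scenario inference over inversions,
    transpositions, inverse transpositions and tandem
    duplication-random loss), a breakpoint-distance neighbor-joining
    tree builder, and seeded synthetic-data generators so that every
    analysis stage can be exercised and verified without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
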