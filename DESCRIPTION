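Package: SeqCompTrends
Title: Genome Sequence Complexity Metrics and Phylogenetic Trend Tests
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes alignment-free genome sequence complexity metrics --
    Sequence Compositional Complexity (SCC) on the four-letter DNA alphabet
    and its SW/RY/KM binary recodings via recursive Jensen-Shannon entropic
    segmentation, the Biobit entropy/anti-entropy decomposition, and the
    chaos-game Genomic Signature -- and tests how such metrics evolve on a
    rooted phylogeny: Blomberg's K phylogenetic signal, phylogenetic Pearson
    correlations with false-discovery-rate control, a root-to-tip trend
    regression calibrated against simulated Brownian evolution, and the
    minimum, ancestor-descendant and sub-clade tests that distinguish driven
    from passive macroevolutionary trends. Includes seeded generators for
    domain-structured synthetic genomes and for Brownian, drifted and
    wall-bounded trait evolution used to validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
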