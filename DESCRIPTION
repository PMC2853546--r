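Package: hapconn
Title: Haplotype Connectivity for Distinguishing Hot-Spots from Melting-Pots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the geographic structure of intraspecific
    genetic diversity from pairwise haplotype distances.  Computes the
    haplotype connectivity HC(Y) of a set of haplotypes (the smallest
    threshold at which the distance-threshold graph becomes connected,
    equivalently the bottleneck value of a minimum spanning tree), its
    exact minimum and maximum over all k-element subsets, and companion
    diversity measures (phylogenetic diversity PD with exact k-subset
    extrema, average squared pairwise distance AD with exact small-n
    extrema, and the genetic diversity spectrum).  Normalized scores rank
    geographic regions so that regions of high diversity can be classified
    as hot-spots (long-term in-situ diversification; low connectivity) or
    melting-pots (secondary contact of divergent gene pools; high
    connectivity).  Includes readers for FASTA alignments, Newick trees,
    haplotype-network edge lists, PHYLIP/TSV distance matrices and
    microsatellite allele profiles, synthetic scenario generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
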