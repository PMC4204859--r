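Package: intronarch
Title: Comparative Analysis of Intron-Exon Architecture Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the intron-exon architecture of orthologous
    genes across taxa. Computes intron phases and exon phase/size notation
    from coding gene models, projects intron insertion sites onto a protein
    multiple sequence alignment to identify homologous sites, clusters and
    labels shared sites by lineage, detects near intron pairs suggestive of
    intron sliding, reconstructs intron gain and loss events by Dollo
    parsimony on a dated species tree, builds neighbor-joining trees from
    p-distances with bootstrap support, and scores translation-initiation
    (Kozak-like) contexts against a frequency-derived consensus. A synthetic
    data generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
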