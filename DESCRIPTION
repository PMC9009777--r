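Package: invphy
Title: Detection of Inter-Paralog Amino Acid Inversions in Duplication Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies multiple-sequence-alignment columns where, after a gene
    duplication, the two paralogous copies carry swapped amino acids in a
    subgroup of species (inter-paralog inversions) or where both copies of one
    species group share a residue that differs from the other group
    (species-specific adaptation). Implements a seven-category probabilistic
    model of post-duplication site evolution on a four-leaf quartet, per-column
    inversion and adaptation scores over pseudo-count-normalised amino-acid
    frequency profiles, a simulated-evolution null (JTT or LG with discrete
    gamma rate heterogeneity) for empirical score thresholds, neighbor-joining
    tree construction from BLOSUM80 distances, a bipartition-matching tree
    similarity, and a synthetic duplication-phylogeny generator with planted
    inversion columns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
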