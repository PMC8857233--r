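Package: phyloscore
Title: Clade-Wise Phylogenetic Turnover Analysis for Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements phyloscore analysis, a per-taxon null-model framework
    that quantifies clade-wise phylogenetic turnover across microbial
    communities. For every ASV that is present in one community of a pair and
    absent from the other, a z-score compares its log nearest-taxon patristic
    distance to a null of random equally-rich communities; per-ASV aggregated
    phyloscores are fed to a phylofactorization that cuts tree edges maximizing
    a two-sample t objective, identifying monophyletic clades under homogeneous
    (HoS) or heterogeneous (HeS) ecological selection. Also provides the
    community-level beta-MNTD/beta-NTI and Raup-Crick (Bray-Curtis) null models
    with assembly-process assignment, screening of clades for putative
    microdiversity (nearest taxon distances, beta-nearest ASV nucleotide
    similarity with the >97% ecotype criterion, per-clade rarefaction), niche
    optima with a Mantel correlogram test of phylogenetic niche conservatism,
    and a synthetic-data generator with planted clade structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
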