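Package: t6sscan
Title: Detection, Phylotyping and Genotyping of Type VI Secretion System Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for surveying type VI secretion
    systems (T6SS) in annotated bacterial genomes. Calls T6SS gene clusters
    from gene-family assignments using a core-gene count and spacing rule,
    builds a concatenated TssB+TssC sheath distance phylogeny and assigns
    clusters to described T6SS subtypes, genotypes the genomic island between
    two flanking marker genes via a gene presence/absence matrix and
    hierarchical clustering, classifies sheath-gene repertoires (standard,
    TssBC fusion, tssC duplication) from VipA/VipB domain architecture, and
    screens proteomes against an effector reference database with identity
    and E-value thresholds. Ships a synthetic annotated-genome generator with
    machine-readable ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    cluster,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
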