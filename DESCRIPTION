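Package: allerGene
Title: Gene Structure, Polymorphism and Epitope Conservation of Mite Group 1 Allergens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence analysis of group 1 allergen genes of house dust mites
    (Der f 1 / Der p 1 and their homologs) from direct-sequenced genomic
    amplicons. Infers exon/intron structure by spliced comparison against a
    cDNA reference, calls polymorphic sites from IUPAC-coded diploid consensus
    sequences, classifies coding substitutions as synonymous or
    non-synonymous, resolves two-haplotype population structure with
    Clark-style phasing, maps variants into the signal/pro/mature preproenzyme
    coordinate system (negative pre-pro numbering, cross-species offsets), and
    scores cross-species conservation of antibody-binding epitopes with
    percent-identity matrices and neighbor-joining trees. Includes a
    synthetic-data generator emulating the gene architecture and diploid
    population structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
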