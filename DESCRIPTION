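Package: qtlcurator
Title: Post-Mapping Curation of Molecular QTL Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the post-mapping stages of a molecular quantitative
    trait locus (QTL) analysis across five transcriptional phenotypes (gene
    expression, exon expression, transcript usage, transcriptional event
    usage and splice-junction usage): genotype quality control including
    X-chromosome dosage harmonisation, trait normalisation (TPM, usage
    ratios, inverse normal transform, GC-trend correction), cis association
    scanning with group-level permutations, fine-mapping-based filtering of
    transcript-level summary statistics via connected components of credible
    sets, signal-level colocalisation from log Bayes factors, and
    genotype-stratified read-coverage plots with intron rescaling. Includes
    seeded synthetic-data generators with planted effects so the whole
    pipeline can be exercised without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    cowplot,
    rlang
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
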