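Package: enhancerTE
Title: Transposable-Element-Derived Enhancer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide analysis of the association between transposable
    element (repeat) annotations and chromatin-predicted enhancers.
    Classifies repeats relative to enhancer anchor positions, quantifies
    their enrichment against local and randomized genomic backgrounds,
    profiles chromatin signal around feature sets with slope-weighted
    rank congruence scores, tests transcription-factor binding motif
    enrichment against a resampled empirical null, relates
    enhancer-associated repeat density to gene expression level and
    tissue specificity, and tests linked genes for gene-set enrichment.
    Includes a seeded synthetic-data generator so every pipeline stage
    is exercisable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Epigenetics, GeneRegulation, Transcription,
    FunctionalGenomics
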