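Package: synforest
Title: Feature-Based Random-Forest Classification of Deleterious Synonymous Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies deleterious synonymous single-nucleotide variants (sSNVs)
    with a feature-based random-forest classifier. Projects variants from VCF onto
    transcript models (GTF) over a reference genome (FASTA), natively computes
    splicing-geometry, exonic-splicing-enhancer, splice-site motif, codon-usage and
    tRNA-adaptation (translation efficiency) features, ingests precomputed
    conservation and splicing-change score tables and annotation tracks (BED),
    assembles a zero-imputed z-score-normalised feature matrix, performs sequential
    backward feature selection under a cross-validated AUC criterion, tunes the
    forest by grid search, and evaluates with the class-ratio-weighted F-measure
    protocol appropriate for heavily imbalanced variant sets. A synthetic fixture
    generator emits toy genomes, gene models, motif and codon resources, score
    tables and labelled variant sets so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    randomForest,
    graphics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
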