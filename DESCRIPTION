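Package: MotifSubtypes
Title: Gene-Motif Based Subtype Discovery from Somatic Point Mutations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers cancer subtypes from catalogs of simple somatic
    point mutations using "gene-motif" features: each single-base
    substitution is reduced to one of the 96 pyrimidine-centred
    trinucleotide classes and concatenated with its gene, giving binary
    sample-by-feature occurrence matrices. The package reads ICGC-style
    SSM tables and VCF, applies empirical top-tail feature selection,
    clusters samples with a recursively applied diagonal Gaussian
    mixture model under BIC, deciphers mutational signatures by
    bootstrap non-negative matrix factorisation, calibrates Fisher
    gene-subtype association with permutation-derived thresholds, and
    characterises subtypes by differential mutation rates, transcript
    rates, clinical composition and Kaplan-Meier survival with the
    weighted log-rank family. A fully seeded synthetic cohort generator
    (reference FASTA, annotation, SSM, clinical tables and ground
    truth) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    cluster,
    survival,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    VariantAnnotation
Config/testthat/edition: 3
biocViews: Software, SomaticMutation, Clustering, Survival, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'catalog-io.R'
    'feature-selection.R'
    'gmm.R'
    'motif-classes.R'
    'motif-engine.R'
    'mutation-stats.R'
    'pipeline.R'
    'signature-nmf.R'
    'simulate.R'
    'subtype-clustering.R'
    'survival-clinical.R'
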