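Package: loopStrength
Title: Predicting the Strength of Cohesin-Mediated Chromatin Interactions
        from 2D Chromatin Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Regression models (deep neural network, random forest, gradient
        boosting) that predict the paired-end-tag (PET) strength of
        cohesin (RAD21)-mediated chromatin interactions between two anchor
        peaks from six easily obtained features: RAD21, H3K27ac and
        H3K27me3 ChIP-Seq signal at the anchors, genomic distance, GC
        content and CTCF motif orientation. Includes the full evaluation
        stack (negative-binomial control interactions, binned contact maps,
        stratum-adjusted correlation, loop-capture analysis with
        shuffled-anchor nulls, permutation and ablation feature importance,
        CTCF occupancy classification, empirical overlap tests) and a
        synthetic-data generator so the whole pipeline can be exercised at
        desk scale without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, HiC, ChIPSeq, Regression, Software
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'features.R'
    'contactmap.R'
    'mlp.R'
    'models.R'
    'evaluate.R'
    'simulate.R'
    'pipeline.R'
    'loopStrength-package.R'
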