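Package: geneTexture
Title: Nucleotide Co-Occurrence Texture Features for Gene Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns DNA sequences (for example, essential genes) into
    fixed-length discriminant feature vectors. Eight nucleotide
    co-occurrence matrices are counted per sequence and summarised with
    five texture statistics (energy, entropy, homogeneity, contrast,
    dissimilarity), yielding a 40-dimensional vector that can be extended
    with Shannon entropy, modified Shannon entropy, a rescaled-range Hurst
    exponent and an indicator-matrix fractal dimension. Labeled sequence
    sets are classified with k-nearest neighbours, decision trees or
    support vector machines under a repeated stratified split protocol,
    optionally after explained-variance PCA reduction, and scored with
    class-size-weighted one-vs-rest metrics. A Markov-chain synthetic
    sequence generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    rpart,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, Sequencing
Collate: 
    'geneTexture-package.R'
    'AllClasses.R'
    'seqio.R'
    'classic.R'
    'patternSets.R'
    'cooc.R'
    'features.R'
    'classify.R'
    'synth.R'
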