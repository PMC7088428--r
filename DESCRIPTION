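Package: mitocompart
Title: Prediction of Sub-Mitochondrial Protein Localization from Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts which of four mitochondrial compartments (inner
    membrane, intermembrane space, matrix, outer membrane) a protein
    resides in, from its amino-acid sequence alone. Sequences are encoded
    as a 239-dimensional feature vector in four named blocks
    (composition/centroid/distribution, split amino-acid composition,
    functional-group and secondary-structure frequencies, and mean
    physicochemical properties), features are ranked by information gain,
    and a radial-basis-function support vector machine is tuned by grid
    search and assessed by stratified k-fold cross-validation with
    per-class sensitivity, specificity, Matthews correlation and ROC/AUC.
    Includes SWISS-PROT-style dataset curation filters, greedy identity
    based redundancy reduction, a Chou-Fasman secondary-structure
    assigner, and a seeded synthetic-data generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ProteinSet-methods.R'
    'utils.R'
    'evaluation.R'
    'feature-selection.R'
    'classifier.R'
    'resources.R'
    'secondary-structure.R'
    'features.R'
    'simulate.R'
    'pipeline.R'
    'sequence-io.R'
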