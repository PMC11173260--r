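Package: enzTopt
Title: Optimal Catalytic Temperature Prediction from Conservation-Masked
    Enzyme Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the optimal catalytic temperature (Topt) of enzymes
    from amino-acid sequence alone. Enzyme families grouped by EC number
    are multiply aligned, fully conserved alignment columns are identified
    and the corresponding residues removed from every member, and
    K-nearest-neighbour regression on composition descriptors (amino acid
    frequency, dipeptide frequency, molecular weight, conjoint triad,
    distribution descriptors) is evaluated by Monte Carlo cross-validation
    with rare-temperature-domain oversampling. Includes a local sequence
    similarity network for sub-grouping weakly conserved families, a
    prediction path for uncharacterised sequences (EC assignment by
    nearest homologue, group-specific conserved-residue stripping), and a
    synthetic protein-family generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    caret,
    randomForest,
    rpart,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'seqdata.R'
    'align.R'
    'conservation.R'
    'enzTopt-package.R'
    'features.R'
    'imbalance.R'
    'modeling.R'
    'ssn.R'
    'predictor.R'
    'synthetic.R'
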