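Package: dtiSubspace
Title: Feature-Subspace kNN Ensembles for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions from protein sequences and
    precomputed small-molecule descriptors. Target proteins are encoded by a
    fragment amino-acid-composition scheme weighted with principal components
    of physicochemical amino-acid properties (AAindex1); drug descriptors are
    partitioned into ordered groups; every (protein-component, drug-group)
    feature subspace trains its own distance-weighted k-nearest-neighbour
    classifier and the grid of classifiers is combined by a unanimity (or
    majority) vote. Includes the negative-pair recoupling sampler, a
    stratified leakage-free cross-validation protocol with confusion-matrix
    metrics, and a synthetic-data generator that plants a subspace-detectable
    interaction signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
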