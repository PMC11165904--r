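Package: mmdsnet
Title: Scalable Metric Multidimensional Scaling with a Minibatch Neural Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metric multidimensional scaling (MDS) for large observation-by-feature
    matrices such as single-cell expression data. The core method trains a small
    fully-connected neural network (one tanh hidden layer, linear output) to
    preserve pairwise distances over minibatches, yielding an explicit map from
    feature space to the embedding space that extends to unseen observations.
    Also provides the classical comparators (SMACOF stress majorization,
    classical MDS/PCA, Gaussian random projection), projected metric MDS with
    its closed-form least-squares projection and an approximation-bound
    diagnostic, seeded synthetic data generators, and readers/writers for
    delimited and Matrix Market files plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
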