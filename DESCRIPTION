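Package: enoseWilks
Title: Wilks Lambda-Guided Principal Component Selection for
    Electronic-Nose Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometrics toolkit for metal-oxide electronic-nose (e-nose)
    sensor arrays. Extracts mean-differential-coefficient features from
    conductance-ratio response curves, performs covariance-based principal
    component analysis, and selects the most discriminative pair of principal
    components by minimising a Wilks Lambda dispersion ratio in both its
    classical form and an absolute-value variant that prevents sign
    cancellation in the off-diagonal scatter entries. Class separability is
    quantified with pooled-covariance Mahalanobis distances between class
    centroids, and classification is validated with a probabilistic neural
    network (Parzen-kernel) classifier including spread-grid selection and
    confusion-matrix reporting. Includes a seeded generator of synthetic
    e-nose datasets, an end-to-end analysis pipeline, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'dataset-io.R'
    'enoseWilks-package.R'
    'features.R'
    'pca.R'
    'pipeline.R'
    'pnn.R'
    'reference-tables.R'
    'separation.R'
    'synth.R'
    'wilks.R'
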