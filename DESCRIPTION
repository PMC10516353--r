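Package: cellpix
Title: Supervised Cell-Type Annotation of scRNA-seq via Gene-to-Pixel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates single-cell RNA-seq query datasets from a labelled
    reference by converting each cell's expression profile into a small
    grayscale image and classifying the images with a convolutional neural
    network. Genes are embedded in two dimensions by similarity (t-SNE, PCA
    or UMAP), enclosed in their minimum-area bounding rectangle via rotating
    calipers, and discretized onto a fixed pixel grid, so that every gene
    owns a pixel and every cell becomes an image. The package covers the full
    pipeline: quality-control filtering on detected genes and mitochondrial
    fraction, regularized Pearson-residual normalization, location/scale
    batch correction, per-gene [0,1] scaling, CNN training with label
    smoothing and early stopping, open-set detection of novel cell types by
    softmax-probability thresholding, and per-class marker-gene extraction
    from gradient-weighted class-activation maps. A negative-binomial
    simulator with planted markers, batch effects, QC violators and a
    held-out novel type makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    Rtsne,
    jsonlite,
    mclust,
    rhdf5,
    stats,
    tools,
    utils,
    uwot,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
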