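Package: cobpheno
Title: Post-Segmentation Phenotyping of Maize Cob Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for extracting phenotypic traits of maize cobs from RGB
    images and instance masks, aimed at genebank phenomics. Reads VGG Image
    Annotator (VIA) polygon annotations or labeled mask images, calibrates the
    pixel scale from two-part rulers, and measures eight traits per cob
    (length, diameter, aspect ratio, asymmetry, ellipticity and mean red,
    green and blue). Includes a classical graph-based instance segmenter
    (Felzenszwalb-Huttenlocher) as a built-in baseline, mask IoU and average
    precision evaluation against ground truth, and two unsupervised clustering
    routes (CLARA with average silhouette on within-image Z-scores; k-means
    with the gap statistic on per-image trait standard deviations) to flag
    phenotypically heterogeneous accessions. A synthetic scene generator with
    analytic ground truth supports testing and benchmarking at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    EBImage,
    cluster,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    optparse
Config/testthat/edition: 3
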