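Package: fpcc
Title: F-Point Transforms, PCCF Similarity and PCA-F Projections for
    Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clustering and 2D visualization toolkit for gene expression
    profiles measured over ordered time points.  Profiles are mapped to
    F-points (the concatenation of the modified cumulative probability of
    the row-normalized profile and of its reversal), on which the PCCF
    correlation measure and the PCA-F projection are defined.  Includes a
    measure-pluggable multi-restart K-means, the PCA-FO rank-blend
    projection, average-silhouette (S1/S2) cluster evaluation, D-plot
    neighborhood-preservation diagnostics, nearest-neighbor maps, a
    Gaussian-population benchmark simulator, delimited-text matrix I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
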