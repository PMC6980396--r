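Package: gbnorm
Title: Graph-Based Between-Sample Normalization of RNA-Seq Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Between-sample normalization of RNA-seq count matrices without
    assuming that most genes are non-differential and without prior knowledge
    of stable reference genes. Reference features are discovered as a densely
    connected community of a thresholded correlation graph over features,
    candidate communities are ranked by the rank-1 residual of their raw
    count submatrix, and samples are scaled by the read-count sum of the
    selected references. Includes classical global scaling baselines (total
    count, upper quartile, trimmed mean of M-values, median-of-ratios,
    iterative Poisson goodness-of-fit), evaluation metrics (precision of
    reference identification and the condition-number based deviation cdev
    from a ground-truth normalization), a synthetic validation-set generator
    with known reference features, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    DESeq2,
    MASS
Config/testthat/edition: 3
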