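Package: trackvst
Title: Variance-Stabilizing Transformations for Genomic Signal Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns the empirical mean-variance relationship of a
    sequencing-based genomic signal (read counts, fold enrichment, or log
    Poisson p-values) from replicate bedGraph tracks and builds a monotone
    transformation that stabilizes variance genome-wide. Provides the
    binned mean-variance estimator with exponential cross-bin smoothing and
    a smoothing-spline fit, the integral variance-stabilizing transform and
    the standard log/asinh alternatives, Gaussian quality-of-fit and
    variance-instability evaluation metrics, a negative-binomial replicate
    track simulator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
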