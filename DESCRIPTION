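Package: clonecna
Title: Allele- and Clone-Specific Copy-Number Deconvolution Across Multiple Tumor Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers allele- and clone-specific copy-number aberrations (CNAs),
    whole-genome duplications (WGDs), and clone proportions jointly across
    multiple bulk DNA sequencing samples from the same patient. Read-depth
    ratios and B-allele frequencies are computed in genomic bins, clustered
    globally along the genome and jointly across samples, scaled to
    allele-specific fractional copy numbers under both a no-WGD and a WGD
    hypothesis, and factored into integer copy-number matrices and clone
    proportions by a constrained coordinate-descent algorithm with an exact
    small-instance solver. A model-selection criterion chooses the number of
    clones and the WGD status. Also provides a counts-level simulator of
    multi-sample bulk tumor sequencing with genome-length-corrected read
    mixing, and a module that tests whether inferred copy numbers explain
    somatic mutation allele frequencies and computes cancer cell fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
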