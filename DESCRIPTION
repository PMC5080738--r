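Package: ddseq
Title: Differential Distribution Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies genes whose expression distributions
    differ between two biological conditions in single-cell RNA-seq data.
    Log-transformed nonzero expression is modelled with a conjugate
    product-partition mixture of normals, yielding a closed-form Bayes
    factor score whose significance is assessed by permutation (optionally
    residual permutation to adjust for covariates such as the cellular
    detection rate). Significant genes are classified into differential
    expression (DE), differential proportion (DP), differential modality
    (DM), or differential modality with different component means (DB)
    using posterior overlap of component means. Includes a test for a
    differential proportion of zeroes, median-of-ratios normalization,
    a negative-binomial mixture simulator with ground truth, and
    evaluation summaries of power, false discovery rate, and
    classification accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    DESeq2,
    Matrix,
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
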