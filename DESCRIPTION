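Package: sendaiqc
Title: Detection and Quantification of Residual Sendai Reprogramming Vector
    Expression in RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-control pipeline for detecting persistent Sendai virus
    (SeV) reprogramming-vector expression in bulk RNA-seq of pluripotent stem
    cells. Builds a combined host-plus-viral transcript reference, assigns
    reads with an exact k-mer voting quantifier, and computes the CDS/UTR
    read-density ratio that discriminates exogenous (UTR-less, vector-derived)
    from endogenous reprogramming-factor transcripts. Includes
    median-of-ratios size-factor, TPM and CPM normalizations, binned coverage
    tracks, a per-passage selection-rate estimator for vector-positive cells,
    and a synthetic read and time-course generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
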