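Package: ribopost
Title: Integrative Post-Transcriptional Analysis of Ribosome Profiling and
    RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for integrative analysis of matched ribosome-profiling
    (Ribo-seq), mRNA-seq and small-RNA-seq experiments: quality control of
    ribosome-protected fragments (feature mapping rates, metagene profiles,
    P-site offset calibration, sub-codon phasing), TMM normalization and
    negative-binomial exact-test differential expression with
    Benjamini-Hochberg correction, translational-efficiency testing via a
    negative-binomial interaction model, classification of per-gene
    regulatory modes (transcriptional, translational, homodirectional,
    opposite, stable) to quantify post-transcriptional buffering,
    sequence-feature stratification (length, GC content, normalized minimum
    free energy, G-quadruplex runs, upstream AUGs, rare-codon frequency)
    with Kruskal-Wallis testing, and small-RNA target analysis (miRNA/tRF
    seed matching, site-count-stratified Kolmogorov-Smirnov CDF comparisons,
    tRNA-derived small RNA classification). Includes a synthetic-data
    generator that plants known regulatory structure so every estimator can
    be validated against recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    MASS
Config/testthat/edition: 3
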