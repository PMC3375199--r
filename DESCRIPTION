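Package: g4prom
Title: Promoter G-Quadruplex Motif Scanning and Expression Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans DNA sequences for putative G-quadruplex (PG4) motifs of
    the form (GGG N1-7)x3 GGG on both strands, anchors motifs to
    transcription start sites within a configurable promoter window,
    selects differentially expressed genes from a probe-by-sample
    expression matrix (quantile normalization, per-probe one-way ANOVA,
    correlation to a condition profile), and quantifies associations
    between promoter quadruplexes and expression change via exact
    hypergeometric enrichment, positional/strand subsets, loop-length
    combination tables, and loop-composition distributions.  Includes a
    seeded synthetic-data generator producing promoter sequences with
    planted motifs and expression matrices with a configurable
    quadruplex/differential-expression odds ratio, so the full analysis
    is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    limma,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
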