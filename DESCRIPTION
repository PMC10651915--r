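Package: dualresponse
Title: Differential-Response Analysis of Dual Confrontation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-level ("response of response") differential
    expression analysis of dual confrontation experiments in which a
    mycoparasitic fungus and a signalling mutant are profiled against a
    universal reference in self- and host-confrontation. Implements
    per-gene linear contrasts with empirical-Bayes variance moderation
    and Benjamini-Yekutieli adjustment, rank-product meta-analysis
    across a bank of normalization methods, an eight-mode regulatory
    classifier with stimulating/suppressing summaries, hypergeometric
    term enrichment with transcriptome-proteome intersection networks,
    and a companion differential-abundance and clustering scheme for
    2D-DIGE proteome spot tables. A synthetic-data generator with
    planted per-gene regulatory modes makes the whole pipeline testable
    without access to the original arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
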