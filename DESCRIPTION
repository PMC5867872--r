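Package: nitronet
Title: Nitrogen-Response Gene Network Inference from Cross-Platform
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing nitrogen-response gene regulatory
    networks from multi-platform microarray experiments. Implements
    probe-to-gene collapse and cross-platform differential-expression
    integration, a two-stage artificial-neural-network procedure that
    ranks genes by single-input phenotype-prediction error and then
    infers a signed, weighted interaction network among the top-ranked
    genes, mutual-information and context-likelihood-of-relatedness
    (CLR) co-expression networks with seed-gene subnetwork extraction,
    graph-theoretic hub analysis with known-interaction overlay, and a
    synthetic-data generator that plants known regulators so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
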