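Package: mpsaltans
Title: Equal-Weights Maximum Parsimony for Small Morphological Matrices,
    with the Drosophila saltans Terminalia Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and heuristic equal-weights maximum parsimony analysis of
    small discrete morphological character matrices (unordered Fitch/Hartigan
    counting). Provides parsers and writers for CSV, TNT-like and minimal
    NEXUS character blocks; exhaustive and branch-and-bound tree search that
    returns every optimal binary topology; a parsimony-ratchet heuristic;
    zero-minimum-length branch collapsing and strict consensus; ensemble and
    per-character consistency and retention indices with truncated-percent
    rendering; exact enumeration of most-parsimonious reconstructions with
    unambiguous-change mapping (synapomorphy, autapomorphy, homoplasy
    classification); and simulators for Mk-style, perfectly compatible and
    column-permuted matrices. Ships the 11-taxon by 19-character male
    terminalia matrix of the Drosophila saltans species group as a worked
    data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
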