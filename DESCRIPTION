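Package: contactGO
Title: Protein Function Prediction from Residue Contact Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) annotations for query proteins from
    predicted residue-residue contact maps. Binned distance-probability maps
    (distograms) are thresholded into contact graphs, reference proteins are
    ranked by a graphlet-degree-signature, sequence-order-preserving graph
    alignment score, and GO terms are transferred from top hits with
    similarity-weighted scoring and top-score normalization. Includes OBO
    ontology parsing with ancestor propagation, information-content weighting,
    CAFA-style Fmax and Smin evaluation, prediction ensembling by score
    averaging, and a seeded synthetic-data generator covering every input
    format so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
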