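Package: grnhybrid
Title: Topology-Driven Hybridness Analysis of Epithelial-Mesenchymal Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates signed gene-regulatory-network topologies with a
    random-parameter ODE ensemble (shifted-Hill kinetics, Euler integration)
    and an asynchronous threshold Boolean model, scores the resulting steady
    states on an epithelial-mesenchymal axis, and relates the frequency of
    hybrid epithelial/mesenchymal phenotypes ("hybridness") to
    topology-level metrics: signed feedback-loop censuses, predicted
    frustration, influence-matrix loop strengths, interconnected
    positive-feedback-loop motifs, and sign-consistency deficit. Includes
    single-edge perturbation sweeps, degree-preserving randomization with
    percentile reports, and a synthetic-network generator for controlled
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
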