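Package: flimresponse
Title: Lymphocyte NAD(P)H FLIM Platform for Predicting Immune Checkpoint
    Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a cell-based platform that
    predicts response to immune checkpoint inhibitors from fluorescence
    lifetime imaging (FLIM) of NAD(P)H autofluorescence in isolated
    lymphocytes. Provides a time-correlated single photon counting (TCSPC)
    decay simulator with instrument-response-function convolution and Poisson
    photon noise, a Poisson maximum-likelihood bi-exponential decay fitter
    recovering the free and protein-bound NAD(P)H components (alpha1, tau1,
    tau2, tau_m), a Shapiro-Wilk-gated treated-versus-control testing
    procedure with sample-level response classification on alpha1 and tau2,
    flow-cytometry activation-marker comparison, reference-normalised qPCR
    log2 fold-change computation, and concordance reporting against iRECIST
    clinical outcome groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pheatmap,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
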