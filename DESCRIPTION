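Package: nanospine
Title: Nanoscale Organization Analysis for Postsynaptic Scaffold Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses of the nanoscale organization of scaffold
    proteins such as AKAP79/150 in dendritic spines. Provides coordinate-based
    cluster analysis of single-molecule localization microscopy data using a
    uniform-randomization density null (high-density region delineation and
    density-based PSD outlining), spatial statistics for immunogold electron
    microscopy annotations (particle-to-membrane distances, synaptic and
    extrasynaptic zone assignment, nearest-neighbor distances, gold-cluster
    detection, conformation classification, label-count fractions), and a
    multi-state diffusion hidden Markov model for single-molecule tracking
    data fitted by expectation-maximization with BIC state selection. Seeded
    synthetic-data generators emulate each input modality with known ground
    truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
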