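Package: caadyn
Title: Stochastic Dynamics and Response-Profile Analysis of the
    Cross-Antagonism-with-Autoregulation Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying decision-making behaviour of the
    cross-antagonism-with-autoregulation (CAA) gene circuit: an exact
    Gillespie simulator of a two-sided promoter/mRNA/protein reaction
    network with tunable repression strength, operator-site number and
    gene dosage; mean-field fixed-point analysis of tristability versus
    monostability; copy-number sweeps that classify stochastic endpoints
    into expression quadrants; a combinatorial multi-operator promoter
    occupancy model quantifying the graded-versus-switch-like averaging
    effect; a flow-cytometry response-profile pipeline (outlier trimming,
    2D binning, Manhattan distances, partitioning-around-medoids
    clustering with silhouette-based model selection, archetype masks);
    Poisson-corrected digital-PCR copy-number estimation with
    delta-method confidence intervals; and seed-deterministic synthetic
    data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
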