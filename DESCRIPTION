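Package: photonhmm
Title: Kinetic Analysis of Single-Molecule Photon Time Traces with Hidden
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood analysis of two-channel
    (donor/acceptor) binned photon-count time traces from single-molecule
    FRET experiments on immobilized molecules. Builds continuous-time Markov
    generator matrices for binding and proline cis/trans isomerization
    schemes with fluorophore blinking, simulates photon traces with exact
    ground truth, fits rate coefficients by binned-photon hidden-Markov
    maximum likelihood with bootstrap errors, decodes state trajectories
    with the Viterbi algorithm, extracts dwell-time statistics and
    single/double-exponential fits, and estimates ligand concentrations from
    fluorescence correlation spectroscopy curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
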