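Package: gpcrmsm
Title: Markov State Model Analysis of GPCR Activation Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conformational-ensemble analysis of G-protein-coupled receptor
    activation from molecular dynamics data: residue-residue contact score
    (RRCS) featurization with contact-change feature selection, time-lagged
    independent component analysis, k-means microstate clustering with
    least-count adaptive-sampling seed selection, Markov state model
    estimation and validation (implied timescales, Chapman-Kolmogorov test,
    cross-validated VAMP-2 scoring), spectral soft coarse-graining into
    metastable states with population and timescale-stability selection
    criteria, transition path theory (committors, reactive flux, mean first
    passage times), kinetic Monte Carlo simulation on transition matrices,
    conditional-probability allosteric coupling, per-residue symmetric
    Kullback-Leibler divergence profiles, mutual-information allosteric
    pathway graphs, trajectory- and frame-level bootstrap error estimation,
    and MSM-weighted free-energy projections. Includes a synthetic-data
    module that generates ground-truth-known trajectories and pseudo-atomic
    receptor structures so every stage of the pipeline can be validated
    without molecular dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    cluster,
    jsonlite,
    graphics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
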