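Package: gpcrdimer
Title: Monomer-Dimer Dynamics of Membrane Receptors from Single-Molecule
    and Ensemble FRET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for studying transient dimerisation of
    membrane receptors (modelled on the neurotensin receptor NTS1) in planar
    lipid bilayers: a lattice-free two-dimensional Monte Carlo simulator of
    receptor diffusion, collision-driven dimerisation and first-order
    dissociation with well-mixed stochastic and mass-action oracles;
    estimation of diffusion coefficients and kinetic constants from
    single-particle track tables (MSD fitting, Saffman-Delbrueck radius
    ratios, Hardt collision frequencies, photobleaching-corrected dimer
    formation rates); ensemble FRET spectral corrections and
    efficiency-distance conversion; single-molecule FRET intensity analytics
    (log-space mixture models with bootstrap BIC, threshold dwell-time and
    survival analysis); and simplex-constrained combination fitting of
    candidate dimer-interface models against FRET efficiency vectors and
    DEER distance distributions, ranked by AIC. A synthetic-data module
    generates track tables, intensity traces, spectra and model matrices
    with the statistical structure the estimators assume, so the entire
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
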