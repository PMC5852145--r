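Package: conewire
Title: Bayesian Reverse Engineering of cGMP Signalling Topologies from
    Growth-Cone Membrane Potentials
Version: 0.1.0
Authors@R:
    person("conewire", "developers", email = "conewire@example.org",
           role = c("aut", "cre"))
Description: Selects, by Bayesian evidence, which of 81 candidate molecular
    interaction topologies between the cGMP effectors (cyclic-nucleotide-gated
    channels, CNGC, and cGMP-dependent protein kinase, PKG) and the
    hyperpolarizing chloride / depolarizing sodium channels best explains
    growth-cone membrane-potential time series. Provides a conductance-style
    forward model with shared (core) and per-cell (peripheral) parameters,
    truncated-normal sparsity priors, random-walk Metropolis posterior
    sampling, stepping-stone marginal-likelihood estimation, leave-one-out
    cross-validation, specificity and late-phase predictability tests, a
    cGMP dose-response simulator, electrophysiology preprocessing (1 Hz
    decimation, step-artifact correction, noise-level estimation), and a
    seeded synthetic-data generator emulating the original study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
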