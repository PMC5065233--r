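Package: redinfo
Title: Redundancy, Noise, and Information Transfer in Threshold Gene Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and information-theoretic analysis of redundant
    arrays of threshold gene-regulatory units (simple regulated, bistable
    autoactivating, and excitable competence-like circuits) driven by a
    common stochastic signal. Implements chemical-Langevin (Euler-Maruyama)
    integration with multiplicative intrinsic noise, stationary
    Fokker-Planck densities and effective potentials for one-dimensional
    units, perturbation layers for extrinsic noise, regulatory cross-talk
    and threshold heterogeneity, plug-in mutual-information estimation in
    bits, scripted scan drivers for noise-resonance, redundancy,
    input-distribution, extrinsic-noise, cross-talk, heterogeneity,
    suprathreshold stochastic-resonance and genetic-load analyses, and
    generators for synthetic graded and Boolean dose-response datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
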