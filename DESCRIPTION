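Package: condensateKMC
Title: Lattice Kinetic Monte Carlo Simulation of Multivalent
    Sticker-Spacer Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven (Gillespie) kinetic Monte Carlo simulation of
    multivalent particles on a two-dimensional periodic lattice, a
    coarse-grained model of sticker-spacer proteins that undergo
    liquid-liquid phase separation.  Particles diffuse, form and break
    valency-limited specific bonds, attract neighbours non-specifically,
    and whole clusters diffuse at a size-scaled rate.  The package
    provides Hoshen-Kopelman cluster labelling, cluster-size and
    intra-cluster-density order parameters, monomer-exchange
    first-passage statistics, kinetic phase-diagram sweeps with
    NoPS/microphase/macrophase classification, and tested evaluators for
    the bead-spring force field (harmonic stretching, cosine bending,
    truncated Lennard-Jones) together with the stochastic specific-bond
    formation and breakage rules used in the underlying Langevin-dynamics
    picture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'bead-spring.R'
    'lattice-core.R'
    'cluster-stats.R'
    'condensateKMC-package.R'
    'kmc-engine.R'
    'observables.R'
    'config-io.R'
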