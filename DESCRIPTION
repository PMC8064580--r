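Package: steerbd
Title: Accelerated Ligand-Binding Protocols on a Brownian-Dynamics Testbed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accelerating and analysing spontaneous ligand binding
    in particle simulations of membrane-transporter binding sites. Implements
    a region- and distance-gated constant-force steering protocol, a
    flat-bottom harmonic containment restraint, and high-concentration
    unbiased sampling, exercised on a seeded overdamped Brownian-dynamics
    engine with a rigid receptor. Includes the matching trajectory
    observables: reference-atom distance series, radial distribution
    functions and cumulative counts around a reference atom, syn/anti
    side-chain conformer occupancy from dihedral angles, binding-event and
    residency detection with hysteresis, and the fraction of simulation time
    spent under bias. Ships a synthetic structure generator emulating an
    aspartate-transporter binding site so every analysis is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
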