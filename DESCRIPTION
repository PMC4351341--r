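Package: AdaptiveQMMM
Title: Adaptive Buffered Force-Mixing QM/MM Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained multiscale molecular dynamics simulator
    implementing adaptive buffered force (AdBF) QM/MM dynamics with two
    interchangeable classical force models standing in for the quantum and
    molecular mechanics engines. Provides hysteretic region partitioning into
    core, dynamical QM, buffer and MM regions, abrupt per-atom force mixing of
    extended and reduced evaluations, momentum-conservation corrections, and
    adaptive Langevin and Nose-Hoover-chains-Langevin thermostats coupled per
    degree of freedom. Includes rational-coordination-number and
    distance-difference collective variables with analytic gradients,
    one-sided and harmonic restraints, umbrella-integration free energy
    profiles with confidence intervals, radial distribution function and
    QM-atom-count diagnostics, buffer-size force-convergence scans, and a
    synthetic water-like box generator used for all test systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
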