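Package: plumecross
Title: Crossing-Triggered Analysis of Insect Plume-Tracking Trajectories
Version: 0.1.0
Authors@R:
    person("plumecross", "maintainers", email = "maintainers@plumecross.org",
           role = c("aut", "cre"))
Description: Tools for studying history dependence in odor plume tracking by
    flying insects. Segments 3D wind-tunnel flight trajectories into plume
    crossings aligned to the experienced concentration peak, computes
    crossing-triggered heading statistics (residualized partial correlations,
    nested binary versus threshold-linear concentration-response models with a
    trajectory-level F-test, early-versus-late history analysis on
    confound-corrected heading changes), and simulates three
    trajectory-generating tracking strategies (reactive surge-cast, Bayesian
    centerline-inferring, and lattice infotaxis) plus a hybrid crossing model
    mixing surge-cast and infotaxis responses. A synthetic trajectory
    generator with injectable concentration and crossing-history effects makes
    the whole pipeline testable by parameter and sign recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
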