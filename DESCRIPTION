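Package: bedplane
Title: Spatial Point-Pattern Analysis of Fossil Bedding-Plane Assemblages
Version: 0.1.0
Authors@R: person("bedplane", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing marked two-dimensional point patterns of
    fossils mapped on bedding planes: polygonal observation windows with
    unobservable gaps, mean and kernel-smoothed intensity, Ripley's K, the
    L-statistic and the pair correlation function with translation edge
    correction, homogeneous and log-linear inhomogeneous Poisson models,
    Thomas cluster and pair-clustering (modified Gauss-Poisson) processes
    with minimum-contrast fitting, Monte-Carlo simulation envelopes and the
    Diggle-Cressie-Loosmore-Ford goodness-of-fit test, circular statistics
    for shell orientations (mean resultant length, Kuiper's test), and a
    synthetic scene generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
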