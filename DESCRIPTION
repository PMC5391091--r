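Package: blswitch
Title: Stochastic Barkai-Leibler Model of Chemotaxis Receptor Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying zero-order ultrasensitivity and intrinsic
    noise in the Barkai-Leibler model of Escherichia coli chemotaxis
    receptors. Provides the activity model and full stochastic reaction
    network for any number of methylation sites, an exact Gillespie
    simulator (direct method, compiled), the quasi-steady-state reduction
    for two methylation sites (drift/diffusion coefficients, free-enzyme
    self-consistency, fixed points, the ligand-independent perfect
    adaptation closed form, and zero-order ultrasensitivity limits), the
    linear-noise approximation around the fixed point (Jacobian, ligand
    sensitivity, Lyapunov covariance, activity variance), linear-response
    functions of activity and flagellar-motor clockwise bias to
    time-dependent ligand changes, and downstream CheY-P/motor noise
    calculators.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
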