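Package: qiffre
Title: Exact Firing-Rate Equations and Spiking Simulators for Inhibitory
    Gamma Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fast (gamma-band) oscillations generated by
    recurrent inhibition.  Implements the exact low-dimensional firing-rate
    equations (rate, mean voltage, synaptic activation) for heterogeneous
    all-to-all networks of quadratic integrate-and-fire neurons with
    Lorentzian-distributed input currents, the classical Wilson-Cowan-type
    heuristic rate equation, and the slow-synapse reduction connecting the
    two.  Companion microscopic simulators (quadratic integrate-and-fire
    and Wang-Buzsaki conductance-based networks, written in C++) allow
    direct micro-macro comparison.  A stability engine computes fixed
    points, characteristic-equation roots, parametric Hopf-bifurcation
    boundaries, and the critical heterogeneity beyond which collective
    oscillations disappear, together with figure-level protocols
    (oscillation amplitude and frequency measurement, phase-diagram sweeps,
    model comparisons under time-varying forcing).
License: MIT + file LICENSE
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
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
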