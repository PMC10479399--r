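Package: talinclutch
Title: Mechanochemical Modelling and Single-Molecule Speckle Kinetics of the
    Talin Elastic Transient Clutch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained mechanochemical model of the Talin linkage between
    flowing F-actin and immobile integrins: folded rod subdomains as Hookean
    springs, unfolded subdomains as freely jointed chains, Bell-law unfolding
    and unbinding (including a two-state catch-slip integrin bond), solved both
    by a discrete-time master equation over unfolded-domain states and by
    explicit overdamped bead-spring pulling simulations with Monte Carlo
    events. Companion single-molecule-speckle (SiMS) analysis tools classify
    speckle trajectories, detect nanometer-scale flow onset, estimate switching
    rate constants by censored Kaplan-Meier survival analysis with
    photobleaching correction, solve the four-state flux-balance clutch model,
    and propagate whole-cell force bookkeeping. A synthetic track generator
    emulates the assumed data-generating process so the full analysis pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
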