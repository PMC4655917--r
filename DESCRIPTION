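Package: channeldcm
Title: Conductance-Based Dynamic Causal Modelling of Synaptic Ion-Channel Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates evoked magnetoencephalographic responses from a
    conductance-based neural mass network with explicit AMPA, NMDA, GABA-A,
    leak-potassium and inward-rectifying-potassium channels, inverts the model
    with a variational-Laplace scheme to recover log-scale channel parameters,
    and provides the group-level diagnostics (intraclass correlation, canonical
    variates analysis, leave-one-out specificity via the non-overlapping
    probability density, ROC/AUC and posterior confidence ellipsoids) used to
    detect virtual channelopathies in synthetic auditory-oddball cohorts.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
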