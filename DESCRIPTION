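Package: ageingGRN
Title: Attractor and Quasi-Potential Landscape Analysis of a p53-Centred
    Ageing Gene Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hill-kinetics ordinary differential equation model of a
    13-gene regulatory network coupling the p53 DNA-damage response to
    Rb-E2F cell-cycle control, together with the analysis machinery used
    to study cellular ageing as movement on a Waddington-style
    epigenetic landscape: deterministic time-course simulation with a
    compiled right-hand side, multistart attractor identification with
    Jacobian stability analysis and phenotype labelling, one- and
    two-parameter saddle-node continuation with fold bracketing and
    hysteresis sweeps, Monte Carlo quantification of the quasi-potential
    U = -ln P(x) over a two-dimensional projection of state space, and
    in-silico edge-deletion perturbations that create or eliminate a
    cancer attractor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
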