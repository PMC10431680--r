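Package: sigbpulse
Title: Stochastic Simulation of the Sigma-B General Stress Response Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for the partner-switching circuit that
    controls the alternative sigma factor sigma-B in Bacillus subtilis. Implements
    the 27-reaction core chemical reaction network and an 11-species extension with
    explicit upstream phosphatase activation noise, three simulation engines
    (deterministic reaction-rate ODE, chemical Langevin SDE via a fixed-step
    drift-implicit Euler-Maruyama scheme, and Gillespie's direct-method SSA),
    automated measures of single-response-pulse and stochastic-pulsing behaviour,
    seeded ensemble parameter sweeps, and deterministic steady-state stability
    scans based on the analytic drift Jacobian.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
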