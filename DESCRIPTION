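Package: lognormkin
Title: Log-Normal Concentration Distributions from Stochastic First-Order Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how log-normal concentration distributions emerge
    from first-order kinetics with a randomly fluctuating rate. Provides the
    closed-form log-normal solution with time-evolving log-space parameters, an
    exact log-space ensemble sampler and an Euler-Maruyama discretization of the
    underlying stochastic differential equation, a Crank-Nicolson Fokker-Planck
    solver for the density evolution, generators for the distribution-shaping
    mechanisms (kinetics, source mixing as mixture or convolution, oscillatory
    external modulation), and distributional diagnostics: log-normality testing,
    maximum-likelihood log-normal fitting, kinetic-parameter recovery from
    time-resolved ensembles, ratio and product propagation of log-normal
    variables, and lifetime estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
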