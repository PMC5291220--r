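Package: tempomem
Title: Temporal Networks, Memory Entropy and Betweenness Preference for Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms scalar or multivariate time series into temporal
    networks by coarse-graining phase space into an equal-size grid and
    recording one time-stamped cell-to-cell transition per sampling step.
    On these networks it implements the memory-entropy analysis (consecutive
    memory networks, entropy growth rate H(tau), and the fitted memory
    exponent rho) and the per-node betweenness-preference mutual-information
    score, together with benchmark signal generators (logistic, Henon,
    Ikeda, Rossler, AR(3), white and 1/f noise) and a logistic-map
    bifurcation experiment comparing rho with the largest Lyapunov exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
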