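Package: relaybounds
Title: Analytic Reliability Bounds for Conductance-Based Relay Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates conductance-based thalamic relay neuron models driven
    by a stochastic pulse train (the driving input) and a sinusoidal synaptic
    conductance (the modulating input), measures empirical relay reliability,
    and computes closed-form lower and upper bounds on that reliability from
    linearized system properties: the transfer-function gain from modulating
    conductance to membrane voltage, the spike-threshold structure (threshold
    current, critical point, refractory period), the success-phase interval of
    the modulating cycle, and the renewal statistics of the pulse train.
    Includes a second-order (T-type calcium plus leak) and a third-order
    (bursting thalamocortical) model with parameters shipped as plain-text
    fixtures, configuration-driven experiment commands, and sweep utilities
    that reproduce bound-containment and trend analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
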