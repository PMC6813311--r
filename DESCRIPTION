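Package: ecxsys
Title: Tri-Phasic Concentration-Response Modelling with System Stress
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits tri-phasic concentration-response relationships observed in
    acute and pulsed ecotoxicity tests by decomposing observed mortality into
    toxicant stress, internal "System Stress" (SyS) and environmental stress
    under the Stress Addition Model (SAM). General stress levels of
    independent stressors are obtained as quantiles of a beta-distributed
    individual stress capacity and combined additively. The toxicant
    concentration-response and the decline of System Stress with toxicant
    stress are both described by four-parameter Weibull curves. The package
    estimates low-effect concentrations (LC5) that monotonic log-logistic
    models miss, provides the monotonic baseline for comparison, a generative
    simulator of tri-phasic survival experiments for validation, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
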