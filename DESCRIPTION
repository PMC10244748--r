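Package: dhdfc
Title: Differential Hebbian Learning with Deep Feedback Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multilayer rate networks whose neurons are driven
    toward target activities by a global proportional-integral feedback
    controller, and trains their feedforward weights with a differential
    Hebbian rule that integrates presynaptic rate times the temporal
    derivative of postsynaptic rate.  Includes the spiking counterpart of
    the rule (pairwise-kernel spike-timing-dependent plasticity on
    inhomogeneous Poisson spike trains), anti-Hebbian pre-training of the
    feedback weights, a supervised predictive-coding variant, diagnostic
    losses (initial mean squared error, feedback cost, and time to
    target), and desk-scale experiments on synthetic classification
    tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
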