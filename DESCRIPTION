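Package: qslum
Title: Quorum-Sensing and Bioluminescence Dynamics in Bacterial Batch Culture
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Four-block kinetic model of a batch culture of luminous bacteria:
    ecological growth on a consumable substrate, Selkov-style energy (ATP)
    metabolism, a LuxR/autoinducer quorum-sensing switch, and a luciferase
    luminescence block. Provides stationary-state and bistability analysis of
    the fast ATP and LuxR subsystems (fold points, hysteresis loops), stiff
    integration of the combined six-variable model, a synthetic-data generator
    for rich- and poor-medium batch scenarios, and a two-stage derivative-free
    (Nelder-Mead) parameter-estimation pipeline with multistart and a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
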