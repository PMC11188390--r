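Package: ddnf
Title: Delayed Negative Feedback Oscillators
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Modelling toolkit for scalar delay differential equations with
    strong delayed negative feedback, the regulatory motif behind delayed
    protein synthesis, hematopoiesis (the Mackey-Glass equation) and related
    physiological oscillators.  Provides a method-of-steps integrator with
    dense interpolable output and event-exact handling of threshold
    nonlinearities, closed-form strong-feedback-limit solutions (sawtooth and
    relaxation limit cycles), Hopf bifurcation machinery for the Hill-type
    feedback (characteristic equations, numerically traced Hopf curves and
    their large-exponent asymptotic approximations), singular-Hopf reduced
    equations of Wright type, and bifurcation-diagram sweeps that compare
    simulation with the analytical approximations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
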