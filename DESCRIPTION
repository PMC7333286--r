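Package: facsim
Title: Formalized Functional-Analysis Case Conceptualizations as Dynamical Systems
Version: 0.1.0
Authors@R:
    person("facsim", "maintainers", email = "maintainers@facsim.dev", role = c("aut", "cre"))
Description: Translates clinical case conceptualizations built with functional
    analysis (the SORKC framework) into systems of coupled ordinary
    differential equations and simulates them. Provides a declarative
    component/term grammar for idiographic dynamical systems, a bundled
    reference model of a panic-disorder patient with Lotka-Volterra style
    panic/avoidance coupling, formalized cognitive-behavioral interventions
    (exposure as a clamp on avoidant coping, cognitive reappraisal as a
    competing functional interpretation, and their combination), adaptive
    Runge-Kutta and Euler integrators, qualitative trajectory-feature
    extraction, and scenario check suites that compare simulated behavior
    against expected clinical phenomena.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
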