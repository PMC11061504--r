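Package: hillmc
Title: Monte Carlo Feasibility Analysis of Hill-Type Muscle Model Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study which Hill-type muscle-tendon-unit parameters must
    be adjusted to model muscular adaptations to unloading (bed rest,
    spaceflight). Implements a tendon-force-state Hill model with calibrated
    characteristic curves, a synthetic right-leg knee-extension model with
    polynomial muscle-tendon kinematics, Legendre-Gauss-Radau direct
    collocation transcription of the isokinetic tracking optimal control
    problem with reserve actuators, a Monte Carlo campaign that perturbs
    grouped muscle parameters within physiological bounds and classifies
    each draw as feasible or infeasible from the knee reserve-moment trace,
    and the downstream analysis: descriptive statistics, kernel densities and
    stepwise logistic regression with McFadden's adjusted pseudo R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
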