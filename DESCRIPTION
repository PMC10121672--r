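Package: mtusim
Title: Hill-Type Muscle-Tendon Simulation of Isokinetic Ankle Dynamometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the human gastrocnemius medialis muscle-tendon unit
    through preloaded and non-preloaded isokinetic ankle-rotation protocols
    using a damped-equilibrium Hill-type model with rigid, typical, and
    highly compliant Achilles tendon variants.  Builds torque-angular-velocity
    profiles sampled at the neutral ankle angle, accounts contractile-element
    work, fits tendon compliance to observed profiles, and provides the
    matching dynamometry/EMG/fascicle processing chain together with a
    synthetic trial generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
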