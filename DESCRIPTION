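Package: rbesim
Title: Cellular Dose-Effect Simulation and Relative Biological
    Effectiveness of Alpha- and Beta-Emitting Radiopharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative biological effectiveness (RBE) of the
    alpha emitter actinium-225 relative to the beta emitter lutetium-177
    for PSMA-targeted radiopharmaceutical therapy at the cellular scale.
    Builds ellipsoidal cell clusters around a central target cell, plans
    per-cell source-point numbers from clinical activity data, simulates
    stochastic DNA double-strand break (DSB) induction and 24-hour repair
    with a desk-scale surrogate of track-structure Monte Carlo, fits
    linear and linear-quadratic dose-effect curves through the origin,
    and evaluates closed-form dose-dependent RBE with delta-method
    uncertainty propagation, isoeffect dose conversion and crossover-dose
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
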