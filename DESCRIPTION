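Package: sphincterFE
Title: Finite-Strain Plane-Stress Modelling of Internal Urethral Sphincter Opening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric two-dimensional finite-element model of the internal
    urethral sphincter under intraluminal pressure, for the computational
    assessment of hole-drilling surgery in primary bladder neck obstruction.
    Provides a synthetic cross-section geometry with tagged tissue regions and
    surgical holes, a graded triangular mesh generator, a five-parameter
    Mooney-Rivlin hyperelastic material with pointwise plane-stress
    condensation, a total-Lagrangian Newton solver with follower pressure
    loading, and post-processing into deformed lumen areas, opening
    loss/recovery percentages, principal stress/strain fields and intraluminal
    boundary profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    interp,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
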