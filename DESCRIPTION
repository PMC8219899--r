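Package: phrelay
Title: Conformational Dynamics and Thermodynamics of pH-Sensitive Calcium Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for inferring pH-relay mechanisms of calcium
    release in C-type lectins from molecular simulation and calorimetry data.
    Provides trajectory featurization (distances, hydrogen bonds, RMSF, RMSD,
    bootstrap-banded histograms), joint principal component analysis and
    time-lagged independent component analysis, density-based
    common-nearest-neighbours clustering, core-set Markov state models with
    milestoning and implied-timescale tests, steered-MD rupture-force
    statistics, right-censored exponential unfolding kinetics, ensemble pKa
    aggregation from PROPKA 3.1 output, and binding free energies from
    isothermal titration calorimetry. A synthetic-data module generates every
    input with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    bio3d,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
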