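Package: oscillobp
Title: Physiologic Simulation and Model-Based Estimation of Oscillometric Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward simulation of cuff pressure oscillations during an
    oscillometric blood pressure measurement, built on a bi-exponential
    artery pressure-volume law coupled to the dynamic compliance of a
    deflating pneumatic cuff, together with the inverse algorithm: beat-wise
    oscillation-envelope extraction, semi-log regression recovery of the
    artery stiffness constants, and a least-squares grid search over
    candidate systolic/diastolic pressure pairs. Includes a registry of
    validation scenarios (varying arterial stiffness and pulse pressure),
    the classical fixed characteristic-ratio baseline for comparison, and
    CSV/JSON/YAML interfaces for recordings, envelopes and scenario
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
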