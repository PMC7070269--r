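Package: actiflow
Title: Activity-Driven Closed-Loop Oxygen Titration from Chest-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of an intelligent portable oxygen
    concentrator software stack. Classifies physical-activity intensity
    (sedentary, light, moderate) in real time from chest-worn 6-channel
    inertial recordings via fixed 3-second windows, 98 time-domain features,
    best-first wrapper feature selection, and a two-node binary hierarchical
    classifier (gain-ratio decision tree and weighted linear discriminant
    analysis), evaluated with leave-one-subject-out cross-validation. A Mealy
    finite-state machine rate-limits flow changes, a seven-profile lookup
    table maps intensity to pulse settings, and a pulse-dose model converts
    settings and breathing rate to bolus volumes. Includes a synthetic IMU
    cohort generator emulating a hospital walking-circuit protocol, SpO2
    summary utilities (CT90/CT85, desaturation events), CSV/JSON/YAML I/O and
    a command-line interface.
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
    MASS,
    rpart,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
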