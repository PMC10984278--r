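Package: finwake
Title: Pectoral Fin Kinematics and Muscle Activity of Fish Station-Holding in a Cylinder Wake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for pectoral fin use by rainbow trout holding
    station in the von Karman vortex street behind a D-section cylinder.
    Reads DeepLabCut-style pose tables and multichannel EMG recordings,
    detects fin-extension events by a body-length-normalized perpendicular
    distance rule, classifies swimming bouts as Karman gaiting or braking,
    measures left-right fin synchronicity by interval overlap, computes
    pre/post fin-extension velocity statistics, detects EMG bursts with a
    two-pass relative-amplitude spike rule, and classifies each fin
    movement as active, passive, or resistive. Includes a synthetic-trial
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
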