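Package: gaitdsp
Title: Fuzzy Grading of Diabetic Polyneuropathy and Surface-EMG Gait Analysis
Version: 0.1.0
Authors@R:
    person("gaitdsp", "developers", email = "gaitdsp@example.org",
           role = c("aut", "cre"))
Description: Tools for grading diabetic sensorimotor polyneuropathy (DSP)
    severity from three routine clinical assessments with a Mamdani fuzzy
    inference system, and for analysing surface electromyography (EMG) of
    lower-limb muscles during the stance phase of gait. Implements zero-lag
    Butterworth filtering, linear-envelope extraction, ground-reaction-force
    based stance segmentation, amplitude and time normalization, extraction
    of temporal and relative-magnitude muscle-activity variables, and
    normality-gated multi-group comparisons with Student-Newman-Keuls post
    hoc testing. A synthetic-cohort generator emulates clinical records and
    raw gait trials with known ground truth so the complete pipeline can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
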