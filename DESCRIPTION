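Package: mastloop
Title: Work-Loop Analysis of Masticatory Muscle Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the mechanical function of jaw muscles
    during mastication from marker-based kinematics, fluoromicrometry and
    electromyography. Provides rigid-body pose estimation and
    joint-coordinate-system jaw rotations, masticatory cycle segmentation
    with fast-closing/slow-closing/slow-opening/fast-opening phase
    classification, fascicle strain from intramuscular bead pairs, EMG
    envelope conditioning with burst onset/offset detection and
    recruitment-scaled stimulation command construction, work-loop measures
    of positive, negative and net mass-specific muscle work and power,
    physiological cross-sectional area and architecture morphospace
    classification, and the accompanying statistics (pooled t-tests and a
    permutation-based one-dimensional curve comparison). A Hill-type muscle
    synthesizer generates ground-truthed trials (markers, EMG, force) so the
    full pipeline can be exercised and validated without in vivo recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
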