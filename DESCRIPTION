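Package: ringcast
Title: Neural-Network Models of Coordinated Middle/Ring-Finger Piano Keystrokes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the coordination between the middle and ring
    fingers during multi-finger piano keystrokes. Extracts metacarpophalangeal
    (MCP) joint flexion angles, angular velocities and accelerations from 3D
    joint-centre trajectories, and fits a single-hidden-layer regression
    network (13 tansig units, linear output) trained with the
    Levenberg-Marquardt algorithm that predicts the ring-finger MCP angle from
    middle-finger motion and, optionally, subject covariates (finger lengths,
    years of piano training). Initial network weights can be optimized with a
    real-coded genetic algorithm or the sparrow search algorithm. A synthetic
    cohort generator emulates metronome-paced keystroke recordings so the full
    pipeline - simulation, kinematics, training, and leave-subject-out
    evaluation with MAE/RMSE/MAPE - runs end to end without access to human
    motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
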