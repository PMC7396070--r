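Package: gaitsynergy
Title: Lower-Limb Intention Prediction from Interlimb Gait Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes sagittal-plane joint angles (shoulder, elbow, hip, knee)
    from Kinect-style 25-joint skeleton streams and trains a from-scratch
    peephole LSTM to predict contralateral hip and knee angle trajectories
    from upper-limb (or upper-plus-lower-limb) angle windows, exploiting the
    interlimb synergy of human gait. Includes a documented CSV/JSON-lines
    skeleton dialect, a synthetic treadmill-gait simulator with contralateral
    phase coupling and sensor jitter, backpropagation-through-time with
    gradient checking, and per-joint per-velocity RMSE reporting across
    walking speeds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
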