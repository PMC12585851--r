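Package: stridecost
Title: Stride-to-Stride Variability and Walking Effort Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying how stride-to-stride variability biases
    simulation-based estimates of walking metabolic cost. Reads multi-stride
    gait time-series (joint angles, joint moments, ground reaction forces),
    detects heel strikes and segments strides, and compares three effort
    estimators: a single random stride, the averaged gait pattern, and the
    mean of per-stride costs. Ships a torque-squared effort model and a
    muscle heat-rate (Umberger-style) energetics model, a synthetic gait
    generator with controllable variability, a feedback-controlled inverted
    pendulum walker with sensory and motor noise, and the comparison
    statistics (percent errors, paired tests, Jensen-gap diagnostics,
    variance scaling with stride count).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
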