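Package: corbeam
Title: Constrained Optimal Resolution Beamforming for Focused Ultrasound
    Neuromodulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational modelling of unintended neuronal excitation during
    low-intensity focused ultrasound (LIFU) neuromodulation.  Provides 2-D
    gridded acoustic media and layered head phantoms, steady-state per-element
    pressure transfer fields (analytic Hankel-function Green's function and a
    finite-difference frequency-domain Helmholtz solver with perfectly matched
    layers), intensity quadratic forms, a pluggable intensity-to-spike-count
    neuronal response model, and the off-target activation area (OTAA) metric.
    Three phased-array beam focusing methods are implemented: conjugate
    (time-reversal) beamforming, an off-target suppression benchmark, and
    constrained optimal resolution beamforming (CORB) via logistic smoothing
    and gradient projection on the fixed-power sphere.  An analytic
    diffraction-limit lower bound on the achievable OTAA in homogeneous media
    is included, together with a config-driven experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
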