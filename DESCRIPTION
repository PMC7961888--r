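Package: emgfb
Title: Surface EMG Biofeedback Simulation, Processing and Game Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building and validating antagonist-ratio surface
    electromyography (sEMG) biofeedback systems without hardware. Includes a
    synthetic two-channel sEMG generator with a low-cost sensor front-end
    model (amplification, supply-midpoint offset, 12-bit quantization),
    a conditioning pipeline (Butterworth bandpass with DC rejection,
    full-wave rectification, windowed smoothing, grip-based calibration and
    normalization), the extensor-ratio statistic with probabilistic game
    scoring, isometric ramp-hold validation protocols with paired tests and
    EMG-force regression, longitudinal session-trend analysis, plain-text
    file formats for all artifacts, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
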