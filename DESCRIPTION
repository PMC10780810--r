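Package: msfadesign
Title: Simulation and Design Toolkit for Snapshot Multispectral Filter Array Cameras
Version: 0.1.0
Authors@R:
    person("ImViA", "Imaging", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating snapshot multispectral
    filter array (MSFA) cameras for plant and vegetation imaging. Optimizes
    spectral band placement with a genetic algorithm driven by Wiener
    reconstruction quality, models the filter/sensor/illuminant imaging
    chain, and performs mosaicking, bilinear demosaicking, Lambertian-white
    calibration, per-band energy balancing, and simulated monochromator
    sweep characterization of hybrid sensors. Includes seeded generators
    for vegetation-like reflectance datasets, sensor quantum-efficiency
    curves and synthetic test scenes, plus spectral evaluation metrics
    (RMS, goodness-of-fit coefficient, CIEDE2000).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
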