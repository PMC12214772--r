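Package: pongscope
Title: Simulation and Reconstruction for Closed-Loop Volumetric Two-Photon
    Tracking Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing and analysing closed-loop two-photon
    recordings of moving, deforming tissue. Generates golden-ratio
    triangle-wave ("Pong") scan trajectories with FPGA counter quantization
    and resonant axial (TAG lens) scanning, simulates a crawling fluorescent
    nerve-cord phantom with ground-truth activity waves that emits Poisson
    photon events, runs a Kalman-filter cylindrical-scan tracker in closed
    loop, reconstructs two-channel rate volumes and movies from photon event
    streams with dwell-time correction, corrects rigid motion, non-rigid
    deformation and intensity fluctuations estimated from the red channel
    alone, and extracts stride-locked traveling-wave statistics (phase
    clocks, stride-averaged cubes, complex PCA wave decompositions and
    ratiometric bout comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
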