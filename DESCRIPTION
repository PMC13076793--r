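Package: pamvasc
Title: Photoacoustic Microscopy Simulation and 3D Angiogenesis Quantification
Version: 0.1.0
Authors@R: person("pamvasc", "developers", role = c("aut", "cre"),
    email = "pamvasc@example.org")
Description: End-to-end simulation and analysis pipeline for optical-resolution
    photoacoustic microscopy (OR-PAM) of microvascular networks in bioprinted
    hydrogel constructs. Generates ground-truth 3D vascular phantoms and
    calibration targets, simulates raster-scanned radio-frequency A-line
    acquisition through a bandlimited focused ultrasound transducer (plus a
    confocal-stack emulator for penetration-depth comparison), reconstructs
    filtered envelope volumes with maximum-amplitude and depth-encoded
    projections, characterizes lateral/axial resolution, transducer bandwidth
    and 1/e^2 penetration depth, and quantifies vessels in 3D: Otsu
    segmentation, depth-binned density, box-counting fractal dimension,
    topological skeletonization with per-segment path lengths, and
    Kruskal-Wallis/Dunn group comparison implemented from the rank formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
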