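Package: mechanoinvade
Title: Quantification Toolkit for Cancer-Cell Mechanics and Basement-Membrane Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements four quantification pipelines for cancer-cell
    mechanics experiments: volumetric basement-membrane invasion from
    multichannel confocal z-stacks (cell segmentation, Teh-Chin dominant-point
    contour approximation, ellipse fitting, 3D convex-hull reconstruction and
    exact percent-volume-below-membrane by tetrahedral clipping); micropillar
    traction-force analysis (beam-theory spring constant, subpixel Gaussian
    spot tracking, stage-drift correction from cell-free reference pillars,
    displacement-to-force conversion and per-pillar peak forces);
    magnetic-tweezers mechanosensing scoring (pulse segmentation, per-pulse
    amplitudes and the pulse-1-to-pulse-12 relative stiffening statistic);
    and AFM compliance analysis (Hertz spherical-indenter model, contact-point
    estimation and Young's-modulus fitting of approach curves). Every
    pipeline is exercisable end-to-end on synthetic phantoms with analytic
    ground truth generated by the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
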