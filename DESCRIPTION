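Package: kmoco
Title: Physics-Informed Simulation, Detection and Correction of Rigid-Motion
    Artifacts in Brain MRI k-Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates rigid-motion corruption of 2D brain MRI slices by
    splicing motion-transformed phase-encoding lines into Cartesian k-space,
    detects the corrupted lines with a U-net over a k-space representation
    (spatial-averaging module, Dice + binary cross-entropy loss), and corrects
    the image with a Swin-block U-net trained under L1, perceptual and k-space
    data-consistency losses. Includes a brain-like phantom generator, a joint
    CPU-scale training harness with a small built-in reverse-mode
    differentiation engine, PSNR/SSIM/NMSE metrics with percentile and BCa
    bootstrap confidence intervals, and one-way ANOVA with Tukey HSD
    between-method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
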