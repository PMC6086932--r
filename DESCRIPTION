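Package: endonano
Title: Nanoscale Geometric Analysis of Endocytic Sites from
    Single-Molecule Localization Data
Version: 0.1.0
Authors@R:
    person("endonano", "maintainers", email = "endonano@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for superresolution (single-molecule
    localization microscopy) images of clathrin-mediated endocytic sites in
    yeast: simulation of raw camera frames and localization tables from
    known ground-truth ring/patch/dome structures, emitter detection and
    pixelated-Gaussian maximum-likelihood fitting under Poisson noise,
    localization grouping, quality filtering, Gaussian rendering, drift
    correction by redundant image cross-correlation, projective dual-channel
    registration, segmentation of cells and endocytic sites, least-squares
    fitting of an erf-based ring/patch model, radial density profiles,
    particle averaging and shape classification, pseudo-temporal staging by
    diffraction-limited marker intensity, side-view temporal reconstruction,
    and the closed-form force and rate laws of actin polymerization at
    endocytic sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
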