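Package: sectionvr
Title: Volume Rendering of Serial Histological Section Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns numbered sequences of stained serial-section micrographs
    into grayscale and true-color volume renderings. Provides reproducible
    replacements for the manual steps of the classical workflow: color
    inversion and background white-point normalization, slice-to-slice stain
    equalization, least-squares rigid slice alignment with configurable
    out-of-bounds fill, separable 3D Gaussian and edge-preserving (nonlinear
    diffusion) smoothing applied per RGB channel, luminance-derived alpha
    channels with parametric transparency transfer functions, colormap
    application for grayscale stacks, and an orthographic emission-absorption
    ray caster with front-to-back alpha compositing. A seeded phantom
    generator produces synthetic section stacks with ground-truth
    misalignment, geometric distortion and staining variation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
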