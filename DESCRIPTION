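Package: texspace
Title: Perceptual Texture Spaces for Procedural Texture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the perceptual dimensions of procedural
    textures. Provides a registry of procedural height-map generators
    (noise, cellular automata, texton placement, reaction-diffusion and
    compositions thereof) with linear parameter sweeps, Lambertian
    rendering under slant/tilt illumination, a synthetic observer that
    simulates free hierarchical grouping and 9-point Likert rating
    experiments from a planted low-dimensional latent space, and the
    downstream analysis: co-grouping similarity matrices, hierarchical
    cluster analysis with level cuts, a truncated-SVD biplot of models
    and perceptual features, an Isomap perceptual texture space with
    residual-variance dimension selection, axis-feature correlation and
    subset robustness analysis, kernel regression from perceptual scales
    to the space, leave-one-out generative-model classification, and a
    recommendation endpoint that suggests a procedural model from
    user-given perceptual scales.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    e1071,
    igraph,
    jsonlite,
    ape,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
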