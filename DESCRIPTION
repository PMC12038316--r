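Package: svcnet
Title: Hierarchical Network Model of Hippocampal Spatial View Cells and
    Scene Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of hippocampal-style spatial view cells
    in a three-layer competitive network of the primate ventromedial visual
    "scene" pathway. A Gabor filter bank encodes 256x256 fixation-patch
    images into V1-like sign-split channels; radius-limited Gaussian
    connectivity and sparseness-constrained threshold-linear competition
    build feature-combination neurons layer by layer (Hebbian or short-term
    memory trace learning); gaze-direction gain modulation places each
    fixation patch into the quadrant of a whole-scene frame; and
    distance-weighted associative recurrent connections in the top layer
    form a continuous attractor for the whole scene, whose activity bump
    moves under neuronal adaptation. Includes synthetic stimulus generation
    (alphanumeric glyph patches, seeded 1/f natural-like images),
    receptive-field mapping by systematic probe presentation, figure-style
    exports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
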