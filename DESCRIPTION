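Package: camophylo
Title: Camouflage Colorimetry, Pattern Granularity, and Phylogenetic
    Comparative Analysis of Background Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying cryptic coloration across related taxa.
    Converts calibrated digital photographs to linear RGB reflectance via
    gray standards and computes region-level color metrics (brightness,
    saturation, and two opponent-channel hue ratios) together with a
    multi-scale Fourier granularity analysis of markings (overall pattern
    contrast, dominant marking size, pattern diversity). Provides
    phylogenetic generalized least squares with maximum-likelihood
    estimation of Pagel's lambda, Felsenstein's phylogenetic independent
    contrasts, and major-axis regression of male contrasts on female
    contrasts to compare sex-specific rates of color-pattern divergence.
    Includes a synthetic-data generator (pure-birth trees, lambda-scaled
    Brownian traits, band-limited textures) so every stage of the pipeline
    can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
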