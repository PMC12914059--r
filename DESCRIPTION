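Package: uvtcell
Title: Label-Free T Cell Characterization from Deep-UV Image Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for label-free T cell
    characterization with deep-UV transmission microscopy. Generates seeded
    synthetic attenuation scenes and image stacks with known ground truth;
    segments cells and partitions them into nucleus and cytoplasm; extracts
    morphological, texture and box-counting fractal features with chi-square
    ranking and UMAP embedding; performs pixelwise temporal-frequency analysis
    of image stacks (first-harmonic phasor g/s decomposition and power-law
    spectral-exponent fitting) to map intracellular dynamic activity; and
    classifies viability/activation state and CD4-like vs CD8-like subtype
    with a compact residual image network and a linear-discriminant baseline,
    including sample-composition estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    e1071,
    jsonlite,
    tiff,
    uwot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
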