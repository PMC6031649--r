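Package: popcontext
Title: Neighbourhood-Aware Single-Cell and Superpixel Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Augments per-object (cell or superpixel) intensity, texture and
    shape features with statistics aggregated over each object's spatial
    neighbourhood, selected either as the K nearest neighbours or as all
    objects within a fixed pixel radius. Provides nuclei/cytoplasm
    segmentation for cell cultures, SLIC superpixel segmentation with
    connectivity enforcement for tissue images, image-level cross-validated
    classification over regular, neighbourhood and combined feature views,
    sweeps over neighbourhood extent and superpixel size, and synthetic
    culture-like and tissue-like data generators with controllable spatial
    phenotype structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    randomForest,
    e1071,
    nnet,
    tiff,
    png,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
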