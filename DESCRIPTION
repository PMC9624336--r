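Package: chromoseg
Title: Segmentation and Morphometry of Nuclei and Chromocenters in
    Fluorescence Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch segmentation of DAPI-stained plant nuclei and their
    heterochromatic chromocenters from confocal z-stacks, with two
    complementary pipelines: a classical one (minimum cross-entropy
    thresholding of a filtered z-projection, distance-transform splitting
    of touching nuclei, 3D structure-tensor eigenvalue features and a
    parameterised hierarchical H-watershed for chromocenters) and a
    deep-learning one (a three-stage U-Net cascade: region proposal,
    nucleus segmentation, chromocenter segmentation, implemented compactly
    in R). Computes per-nucleus heterochromatin morphometrics (HF, RHI,
    RHF, per-chromocenter area fractions), tri-level annotation masks,
    Dice-based mask comparison, and includes a seeded generator of
    synthetic DAPI-like scenes with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, EBImage, tiff, png, jsonlite
Suggests: testthat (>= 3.0.0), withr, mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
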