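Package: TumorFusion3D
Title: Three-Dimensional Fusion of Histopathology and MRI Tumor Models from
    Resected Soft-Tissue Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs a three-dimensional histopathological tumor model
    from the pathologist's grossing-plane outlines by signed-distance
    shape-based interpolation, converts an MRI tumor segmentation (binary
    label volume, NIfTI or NRRD) into a watertight surface mesh,
    superimposes both bodies into the optically scanned specimen's frame
    with a closed-form landmark (Kabsch/Umeyama) rigid or similarity
    transform, and reports per-case and cohort volumetric and dimensional
    comparisons (volumes, anterior-posterior / cranial-caudal / left-right
    extents, greatest surface diameter, differences, ratios). Includes a
    seeded synthetic phantom generator (specimen and tumor meshes, MRI-style
    masks, grossing contours, landmark pairs with known ground-truth
    transform) so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
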