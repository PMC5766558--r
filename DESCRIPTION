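Package: subsolidseg
Title: Vessel and Solid-Core Segmentation in Subsolid Pulmonary Nodules on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise characterization of subsolid pulmonary nodules on
    computed tomography. Given a CT volume and a nodule segmentation, every
    nodule voxel is labeled as vessel, solid core, or ground-glass using
    multi-scale Hessian-eigenvalue and intensity features, a k-nearest-
    neighbour posterior classifier with an optimized class-weight operating
    point, and an anatomically constrained vascular-continuity regularization
    that penalizes vessel calls whose local diameter is implausible relative
    to the vessel entering the nodule. Includes image standardization
    (isotropic resampling and reconstruction-kernel band normalization), a
    seeded synthetic phantom generator with ground-truth labels, and the
    detection and voxel-overlap evaluation protocol (Cohen's kappa,
    sensitivity, precision, Dice).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    class
Config/testthat/edition: 3
NeedsCompilation: yes
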