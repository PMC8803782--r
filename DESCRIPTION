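Package: mediastinet
Title: Automated Detection of Pathological Mediastinal Lymph Nodes in FDG-PET/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated two-phase pipeline that localises pathological
    mediastinal lymph nodes in whole-body [18F]FDG-PET/CT scans. The thorax is
    located from the CT by morphological lung segmentation, a 2D U-Net trained
    on spherical surrogate labels proposes candidate regions at high
    sensitivity, and a 3D residual network classifies overlapping 64-mm cubes
    whose per-voxel summed scores yield the final predicted nodes. Includes a
    parametric thoracic phantom simulator with two scanner profiles for
    training and testing without patient data, and node-level evaluation:
    sensitivity, false positives per patient, Cohen's kappa under a fixed
    nodes-per-patient true-negative convention, and exact Clopper-Pearson
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
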