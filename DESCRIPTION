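Package: longdbm
Title: Longitudinal Deformation-Based Morphometry with Phantom Validation
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying longitudinal brain atrophy from paired
    structural volumes using symmetric diffeomorphic registration and
    Jacobian-determinant (JD) maps. Includes a synthetic longitudinal phantom
    generator with known ground-truth deformation for end-to-end validation,
    voxelwise group inference with threshold-free cluster enhancement (TFCE)
    and Freedman-Lane permutation correction, subject-level cohort statistics
    (adjusted group models, hierarchical variance partitioning, sulcus-versus-
    gyrus mixed-effects interaction, Spearman correlations with FDR), and
    atrophy-endpoint clinical-trial power calculations based on Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    lme4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
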