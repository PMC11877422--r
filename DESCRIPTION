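Package: longipred
Title: Individualised Prediction of Longitudinal Change in Volumetric Brain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting individualised longitudinal change in
    volumetric brain-imaging modalities from baseline images. Provides the
    closed-form null and expected prediction correlations for temporal
    difference maps, residualisation of the population-average pattern, the
    residual temporal difference metric, a synthetic longitudinal cohort
    generator with known ground truth, a 3D U-Net image-to-image regressor
    with modality weighting and an uncertainty-weighted voxel-wise loss, a
    gradient-based weighted saliency explainer, and evaluation protocols
    including the change-versus-denoising diagnostic, fingerprint
    identification, and phenotype prediction from change maps via principal
    components and elastic-net regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
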