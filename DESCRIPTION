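Package: iscn
Title: Individual Structural Connectivity Networks from Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds individual structural connectivity networks from
    diffusion-weighted MRI: voxel-wise diffusion-tensor fitting with
    fractional-anisotropy and mean-diffusivity maps, deterministic
    tensor-deflection (TEND) streamline tractography, atlas-based network
    construction with fiber-density, FA and MD edge attributes, and
    cross-validated two-group classification of the resulting networks via
    information-gain feature selection with maximum-margin, correlation
    k-nearest-neighbor and naive Bayes classifiers. Includes a synthetic
    phantom generator (fiber-bundle DWI volumes with ground-truth tensors, and
    cohorts of connectivity matrices with planted group effects) so the whole
    pipeline can be exercised and validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
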