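Package: coordnet
Title: Coordinate Network Mapping of Brain Abnormalities with Normative
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps published neuroimaging-abnormality coordinates to common
    brain networks using a normative functional connectome. Implements
    coordinate network mapping (spherical seeds, seed-to-voxel Pearson
    connectivity, group t-maps, signed thresholding, and study-overlap
    maps), activation likelihood estimation (ALE) meta-analysis with
    permutation-based cluster family-wise-error control, specificity
    testing against random-coordinate nulls with voxelwise permutation
    inference and false-discovery-rate correction, multimodal validation
    statistics (ROI overlap with parcel-based nulls, spatial correlations,
    ROI-to-ROI connectivity, network-profile ANOVA), and stimulation-site
    network analyses with clinical-outcome weighting. Ships a synthetic
    connectome generator with planted ground truth so the full pipeline
    runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
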