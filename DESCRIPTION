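Package: spectharm
Title: Gamma-Camera Harmonization and Z-Score Mapping for Brain Perfusion SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to study and correct inter-camera differences in brain
    perfusion SPECT. Generates digital brain phantoms (Hoffman-style layered
    gray/white, skull-attenuated gray-matter-only, uniform pool) and synthetic
    normal-subject cohorts; simulates reconstruction-domain acquisition on
    parameterized gamma cameras (attenuation, spatially varying sensitivity,
    PSF blur, Poisson noise, Butterworth post-filter, first-order Chang
    attenuation correction); builds voxel-wise count-ratio compensation maps
    between cameras and applies them to subject volumes; constructs
    normal-database mean/SD volumes and voxel-wise Z-score maps; computes
    VOI-based Severity/Extent/Ratio indices; and evaluates correction quality
    with voxel-wise two-sample t-maps (height and cluster-extent thresholds),
    central/marginal summaries and region-wise count correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
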