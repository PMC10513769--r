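Package: ranometry
Title: Automated Bidimensional and Volumetric Tumor Burden Measurement
    for Longitudinal Response Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures contrast-enhancing tumor burden on 3D segmentation
    label maps (NIfTI) the way neuro-oncology response criteria prescribe:
    per-lesion bidimensional Macdonald/RANO measurements on axial slices
    (sub-voxel contouring, exhaustive contained longest-diameter search and
    largest perpendicular diameter within an angular tolerance), a 2.5D
    variant with an unconstrained longest 3D diameter and a perpendicular
    plane sweep, voxel-count volumetry and Wadell sphericity. Aggregates
    lesions into the sum of perpendicular-diameter products (SPD) with
    optional measurability and target-lesion filters, and assesses
    longitudinal series: trend agreement, Spearman rank correlation,
    consistency intraclass correlation, nadir-referenced time-to-progression
    under configurable thresholds, threshold sweeps and TTP-overall-survival
    correlation. Ships a deterministic phantom generator (spheres,
    ellipsoids, boxes, fragmented shells, multifocal scenes, growth series)
    with analytically known geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
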