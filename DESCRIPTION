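Package: flywalk
Title: Automated Morphometric Phenotyping and Feature-Based Sorting of
    Walking Flies from Two-Channel Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch image-analysis pipeline for morphometric phenotyping of
    single walking fruit flies imaged in a backlit tunnel with a two-channel
    (blue silhouette / red transillumination) strobe scheme. Validates frames
    (focus, border clearance, reflections, orientation, alignment, symmetry),
    aligns the silhouette stack by central image moments, removes moving legs
    with a temporal 95th-percentile projection, splits the body into head,
    thorax and abdomen by marker-controlled watershed, calls sex by fusing
    abdominal-luminance template correlation with sex-comb detection, measures
    interocular distance from ocelli landmarks and eye-edge contrast, and
    quantifies wing length, width and area by fitting a B-spline outline and
    longitudinal-vein (L2-L5) template to the topological skeleton of the wing.
    Includes robust bi-square regression agreement statistics against manual
    measurements, per-sex ranking and top/bottom selection on relative wing
    size, and a parametric synthetic fly renderer that provides exact ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    splines,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
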