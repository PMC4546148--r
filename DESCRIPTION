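Package: notchmorph
Title: Morphometry of the Lateral Femoral Notch Sign from Knee MRI
    Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies impaction fractures of the lateral femoral condyle
    (the "lateral femoral notch sign") from sagittal MRI slice
    segmentations and lateral-radiograph condyle profiles.  Measures
    radiographic sulcus depth with the tangential-line technique, bridges
    the depressed portion of each slice contour to recover the
    pre-injury bone surface, reconstructs the subchondral bone surface in
    3D from stacked planar contours, and reports defect extent, depth,
    primary (bridged) and concave surface areas, and volume, localized to
    six anatomical segments of the condyle.  Includes a synthetic condyle
    phantom with spherical-indentation defects whose areas, volume and
    depth have closed forms, used as ground truth for validation, plus
    cohort screening, summary tables and internal-consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
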