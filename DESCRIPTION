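Package: woundarea
Title: Automatic Wound Area Measurement from RGB-D Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the surface area of wounds (pressure injuries) from a
    segmentation mask and a co-registered depth image, as captured by a
    LiDAR-equipped camera. The wound border is traced from the mask,
    back-projected through the pinhole camera model into 3D world
    coordinates, fitted with a least-squares plane, and the area is
    computed by the tilt-corrected shoelace formula on the projected
    contour. Also provides pixel-level segmentation evaluation metrics
    (Dice, IoU, precision, recall, accuracy, Dice loss), relative-error
    statistics for manual-versus-automatic area comparisons with a bundled
    clinical reference table, a synthetic RGB-D scene generator with known
    ground-truth area for validation, and file-level entry points for
    LabelMe annotations, PNG masks, and 16-bit PNG or plain-text depth
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
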