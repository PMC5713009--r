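Package: footmorph
Title: Plantar Footprint Morphometry from Podoscope Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of plantar footprints captured on an
    optical podoscope. Segments the plantar contact region from an RGB
    image by CIELAB colour thresholding, calibrates pixels to centimetres
    with a 1 cm2 fiducial square, locates the anatomical key points of the
    footprint by boundary scans, and computes the Staheli arch index, the
    Chippaux-Smirak index and Clarke's angle, classifying each foot into
    five deformity groups from cavus to flat. Includes a parametric
    synthetic-footprint generator with analytic ground truth, precision
    statistics (sigma-rule checks, Pearson correlation, method agreement),
    longitudinal patient-history storage and plotting, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
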