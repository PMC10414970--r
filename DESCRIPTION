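Package: rhizopH
Title: Ratiometric Quantification of Root Surface pH from Dual-Excitation
    Fluorescence Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to turn two-excitation-channel (488/405 nm) fluorescence
    images of plant roots in dye-stained medium into longitudinal
    root-surface pH profiles. The root is segmented as the dark
    (dye-excluded) object in bright medium, a surface band 10-25 px off
    the root is extracted with an exact Euclidean distance transform, and
    the F488/405 excitation ratio is binned along the midline arc length
    from the tip. Includes monotone ratio-pH calibration, gravitropic
    kinematics (tip angle, elongation rate, lower/upper flank asymmetry,
    pH oscillations), alkaline-domain descriptors and alkalinization
    factors, rank-based (Brunner-Munzel) per-position profile comparison,
    mesh-penetration efficiency, and a fully ground-truthed synthetic
    phantom generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, ImageImport
RoxygenNote: 7.3.3
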