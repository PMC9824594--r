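Package: microscaff
Title: Parametric Scaffold Toolpaths, G-Code Generation and Microfiber
    Metrology for FDM Tissue-Engineering Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates deposition routines (G-code) for porous
    tissue-engineering scaffolds printed on standard fused deposition
    modeling (FDM) printers. Builds rectilinear and triangular lattice
    toolpaths from primitive geometric patterns, assigns the extruder
    axis (E) with a volumetric flow model based on a stadium-shaped
    strand cross-section, emits and parses a RepRap-flavour G-code
    subset, encodes parameter-sweep experiment matrices including
    under-extruded surface passes deposited without raising the Z axis,
    validates settings against printability rules, and measures fiber
    diameters on calibrated micrographs with a synthetic micrograph
    generator for closed-loop testing.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
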