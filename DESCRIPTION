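Package: uvholo
Title: UV Lensless On-Chip Holographic Microscopy Toolkit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational core for lensless in-line holographic microscopy
    at deep-UV illumination (266 nm): angular-spectrum field propagation,
    forward simulation of sub-pixel-shifted in-line holograms on a Bayer
    CMOS sensor (including coherent parasitic fringes and speckle from
    out-of-sample planes), shift-and-add pixel super-resolution with
    circular-averaging noise suppression, holographic reconstruction with
    autofocus and digital object peeling for twin-image removal,
    background-compensated multi-height nanoparticle detection with
    parabola focus-criteria validation, and a Mie-series forward-scattering
    radar-cross-section calculator for perfect-electric-conductor
    nanospheres with a cross-wavelength equivalent-diameter solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, EBImage, tiff, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization
RoxygenNote: 7.3.3
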