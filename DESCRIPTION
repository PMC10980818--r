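Package: propsim
Title: Simulation and Analysis of Projective Light-Sheet Imaging with
    Parameter Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward model of projective light-sheet microscopy with parameter
    selection (props): a tilted light sheet is swept across the sample during a
    single camera exposure while the image is sheared across the chip, and a
    rolling shutter synchronized to the shear selects an axial sub-volume
    ("slab") whose depth, position and viewing angle follow in closed form from
    the shutter width, the shutter-versus-sweep delay and the shear rate.
    Includes the closed-form geometry (slab bounds, viewing angle, nonlinear
    galvo waveform design for curved-surface projections), a voxel-level
    acquisition simulator, seeded synthetic phantoms (beads, vessels, curved
    shells, two-layer calcium movies, scattering haze), a digital shear-warp
    slab/curved renderer used as an independent oracle, and downstream analyses
    (dF/F traces, kymographs, static-background subtraction,
    signal-to-background ratio, shear-galvo calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
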