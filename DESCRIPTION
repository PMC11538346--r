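Package: flipr
Title: Simulation and Analysis of Flipped-Image Remote-Focusing Volumetric Voltage Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for volumetric voltage imaging acquired with a flipped-image
    remote-focusing (FLIPR) light-sheet microscope. Provides closed-form
    calculators for the remote-focusing optical design (magnification,
    retroreflector NA limit, field of view, light-sheet Rayleigh length), a
    forward simulator of the continuous-sweep rolling-shutter acquisition
    geometry (tilted optical planes, up/down-stroke lateral shift, exposure
    jitter, photobleaching, shot and read noise), preprocessing (exposure-jitter
    detection and correction, rigid subpixel motion correction), stitching of
    tilted half-planes into a consistent 3D reference volume, 3D cell-body
    segmentation, iterative weighted-sum extraction of per-neuron voltage
    traces with spike detection and automated curation, and bead-based PSF
    characterization plus light-sheet-to-focus calibration. Synthetic
    acquisitions with full ground truth support end-to-end validation of the
    reconstruction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
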